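# Synthetic fixture taxonomy for food-source assignment tests and simulations.
# Small stand-in tree (not real NCBI taxonomy): bloodmeal and plant families
# with one or two species each, plus Arthropoda (host exclusion), Fungi
# (discard rule) and a viral clade. Ranks: superkingdom, kingdom, phylum,
# class, order, family, genus, species.
taxon_id	parent_id	rank	name
1	1	no rank	root
2	1	superkingdom	Eukaryota
3	1	superkingdom	Viruses
4	3	clade	Riboviria
10	2	kingdom	Metazoa
11	2	kingdom	Viridiplantae
12	2	kingdom	Fungi
20	10	phylum	Arthropoda
21	20	class	Insecta
24	21	order	Diptera
22	24	family	Culicidae
26	22	genus	Aedes
27	26	species	Aedes albopictus
28	22	genus	Culex
29	28	species	Culex pipiens
23	10	phylum	Chordata
30	23	class	Mammalia
31	23	class	Aves
32	23	class	Actinopteri
40	30	family	Hominidae
50	40	genus	Homo
60	50	species	Homo sapiens
51	40	genus	Pan
61	51	species	Pan troglodytes
41	30	family	Bovidae
52	41	genus	Bos
62	52	species	Bos taurus
53	41	genus	Bubalus
63	53	species	Bubalus bubalis
42	30	family	Canidae
54	42	genus	Canis
64	54	species	Canis lupus
43	30	family	Muridae
55	43	genus	Mus
65	55	species	Mus musculus
56	43	genus	Rattus
66	56	species	Rattus norvegicus
44	31	family	Phasianidae
57	44	genus	Gallus
67	57	species	Gallus gallus
45	32	family	Salmonidae
58	45	genus	Salmo
68	58	species	Salmo salar
59	45	genus	Oncorhynchus
69	59	species	Oncorhynchus mykiss
33	11	phylum	Streptophyta
34	33	class	Magnoliopsida
46	34	family	Fabaceae
70	46	genus	Glycine
80	70	species	Glycine max
71	46	genus	Lupinus
81	71	species	Lupinus albus
47	34	family	Poaceae
72	47	genus	Oryza
82	72	species	Oryza sativa
48	34	family	Musaceae
73	48	genus	Musa
83	73	species	Musa acuminata
49	34	family	Salicaceae
74	49	genus	Salix
84	74	species	Salix alba
75	49	genus	Populus
85	75	species	Populus trichocarpa
76	34	family	Paeoniaceae
77	76	genus	Paeonia
86	77	species	Paeonia lactiflora
35	12	phylum	Ascomycota
36	35	class	Saccharomycetes
78	36	family	Saccharomycetaceae
79	78	genus	Saccharomyces
87	79	species	Saccharomyces cerevisiae
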