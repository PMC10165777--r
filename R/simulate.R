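# Seeded synthetic-data generator with planted ground truth. Emulates the
# study design this package targets: libraries of 15 mosquito species over
# 13 locations x 3 years, viral contigs mutated from a mock reference set to
# controlled amino-acid/nucleotide identities, species-specific virus sets
# with vertical (all-years) and environment-derived (mosaic) presence,
# food-source contigs drawn from the fixture taxonomy, and planted
# virus-food co-occurrences. Hit tables are generated directly from the
# planted mutations (no external aligner), so the parsing and filtering
# paths are exercised end to end.

SPECIES_CODES <- c("Ae.alb", "Cx.pip", "Ar.sub", "Cx.tri", "Ae.aeg",
                   "Cx.pal", "Ae.vex", "Cx.vis", "Cx.fus", "Cx.sit",
                   "Cx.pse", "An.vag", "Cx.lut", "Ae.mal", "Cx.gel")
LOCATION_CODES <- c("BS", "DF", "DZ", "HK", "LD", "LG", "LS", "QH", "SY",
                    "TC", "WC", "WN", "WZS")

# Family -> species taxon ids of the fixture taxonomy.
METAZOA_FAMILIES <- list(Hominidae = c("60", "61"), Bovidae = c("62", "63"),
                         Canidae = "64", Muridae = c("65", "66"),
                         Salmonidae = c("68", "69"))
PLANT_FAMILIES <- list(Fabaceae = c("80", "81"), Poaceae = "82",
                       Musaceae = "83", Salicaceae = c("84", "85"),
                       Paeoniaceae = "86")
ARTHROPOD_ROOT <- "20"
FUNGI_ROOT <- "12"
FUNGAL_SPECIES <- "87"
ARTHROPOD_SPECIES <- c("27", "29")

#' The fixture taxonomy shipped with the package
#'
#' A small synthetic taxonomy (about 60 nodes, not real NCBI data) with the
#' bloodmeal and plant families used by the simulator, an Arthropoda clade
#' for the host-exclusion rule and a Fungi clade for the fungi-discard
#' rule.
#'
#' @return a [taxonomy_tree()].
#' @export
fixture_taxonomy <- function() {
  read_taxonomy(system.file("extdata", "food_taxonomy.tsv",
                            package = "viromeflow", mustWork = TRUE))
}

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 15 mosquito species, 13
#' locations, three sampling years (2018-2020) and 200 sequencing
#' libraries. Identity targets for known viruses are placed well above the
#' novelty thresholds and for novel viruses well below (at least 2
#' percentage points away), so every planted label is unambiguous.
#'
#' @param seed integer seed; fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param n_species,n_locations,years,n_libraries study design.
#' @param reads_per_library mean non-rRNA read total per library (the
#'   simulation runs at desk scale, far below real sequencing depth).
#' @param n_known_viruses,n_novel_viruses planted virus counts.
#' @param ref_length_range reference coding-sequence length range (nt).
#' @param rpm_range expected RPM range for present viruses (log-uniform).
#' @param nb_dispersion negative-binomial dispersion of mapped-read counts
#'   (variance = mu + dispersion * mu^2); overdispersed counts are the
#'   realistic stress case.
#' @param planted_cooccurrences data.frame with columns `virus`, `family`,
#'   `strength`: probability of the food family in libraries containing
#'   the virus (background probability elsewhere is 0.05).
#' @param spurious_rate fraction of absent (OTU, library) cells that still
#'   receive a few stray reads at low reference coverage.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_species = 15, n_locations = 13, years = 2018:2020,
                       n_libraries = 200, reads_per_library = 1e6,
                       n_known_viruses = 8, n_novel_viruses = 7,
                       ref_length_range = c(900, 1500),
                       rpm_range = c(100, 2000), nb_dispersion = 0.5,
                       planted_cooccurrences = data.frame(
                         virus = "v01", family = "Bovidae", strength = 0.9,
                         stringsAsFactors = FALSE),
                       spurious_rate = 0.05) {
  if (n_species > length(SPECIES_CODES) ||
      n_locations > length(LOCATION_CODES))
    stopf("at most %d species and %d locations are supported",
          length(SPECIES_CODES), length(LOCATION_CODES))
  if (n_known_viruses < 1 || n_novel_viruses < 1)
    stopf("need at least one known and one novel virus")
  structure(list(seed = as.integer(seed), n_species = n_species,
                 n_locations = n_locations, years = years,
                 n_libraries = n_libraries,
                 reads_per_library = reads_per_library,
                 n_known_viruses = n_known_viruses,
                 n_novel_viruses = n_novel_viruses,
                 ref_length_range = ref_length_range,
                 rpm_range = rpm_range, nb_dispersion = nb_dispersion,
                 planted_cooccurrences = planted_cooccurrences,
                 spurious_rate = spurious_rate),
            class = "sim_config")
}

# Sense (non-stop) codons of the standard genetic code.
.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Simulate a mock known-virus reference set
#'
#' Random coding sequences (start codon, sense codons, one stop) with
#' stable ids `ref_v01`, `ref_v02`, ... One reference per planted virus;
#' they form the search targets for the planted identities.
#'
#' @param config a [sim_config()].
#' @return a [Biostrings::DNAStringSet] of references.
#' @export
simulate_reference_set <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_known_viruses + config$n_novel_viruses
  sense <- .sense_codons()
  seqs <- vapply(seq_len(n), function(i) {
    n_codons <- round(stats::runif(1, config$ref_length_range[1],
                                   config$ref_length_range[2]) / 3)
    paste0(paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)),
                 collapse = ""), "TAA")
  }, character(1))
  refs <- Biostrings::DNAStringSet(seqs)
  names(refs) <- sprintf("ref_v%02d", seq_len(n))
  refs
}

# Mutate a coding sequence to hit amino-acid and nucleotide identity
# targets (percent). Amino-acid changes are single middle-base
# substitutions; extra nucleotide divergence comes from synonymous
# third-position swaps. No indels, so identity equals the fraction of
# unchanged positions.
mutate_to_targets <- function(coding, aa_target, nt_target) {
  gc <- Biostrings::GENETIC_CODE
  stopifnot(nchar(coding) %% 3 == 0)
  codons <- substring(coding, seq(1, nchar(coding) - 2, 3),
                      seq(3, nchar(coding), 3))
  body <- which(.translate_codons(codons) != "*")[-1]  # keep start codon
  n_aa <- length(codons) - 1L   # exclude the stop from aa accounting
  n_nt <- nchar(coding)
  n_aa_mut <- round((1 - aa_target / 100) * n_aa)
  n_nt_mut <- round((1 - nt_target / 100) * n_nt)
  n_syn <- n_nt_mut - n_aa_mut
  if (n_syn < 0)
    stopf("identity targets unreachable: aa %.1f%% needs more nt changes than nt %.1f%% allows",
          aa_target, nt_target)
  if (n_aa_mut + n_syn > length(body))
    stopf("identity targets unreachable: %d changes exceed %d mutable codons",
          n_aa_mut + n_syn, length(body))

  picked <- sample(body, n_aa_mut + n_syn)
  aa_sites <- picked[seq_len(n_aa_mut)]
  syn_sites <- setdiff(picked, aa_sites)
  bases <- c("A", "C", "G", "T")
  for (i in aa_sites) {
    cod <- codons[i]
    old_aa <- gc[[cod]]
    for (b in sample(setdiff(bases, substr(cod, 2, 2)))) {
      cand <- cod
      substr(cand, 2, 2) <- b
      if (gc[[cand]] != old_aa && gc[[cand]] != "*") {
        codons[i] <- cand
        break
      }
    }
  }
  informative <- names(gc)[gc != "*"]
  for (i in syn_sites) {
    cod <- codons[i]
    fam <- informative[gc[informative] == gc[[cod]] &
                         substr(informative, 1, 2) == substr(cod, 1, 2) &
                         informative != cod]
    if (length(fam)) codons[i] <- sample(fam, 1)
  }
  paste(codons, collapse = "")
}

# Hamming identities (percent) between equal-length coding sequences,
# on nucleotides and on translated amino acids (stop excluded).
.measure_identities <- function(a, b) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  nt <- 100 * mean(sa == sb)
  ta <- .translate_codons(substring(a, seq(1, nchar(a) - 2, 3),
                                    seq(3, nchar(a), 3)))
  tb <- .translate_codons(substring(b, seq(1, nchar(b) - 2, 3),
                                    seq(3, nchar(b), 3)))
  keep <- ta != "*" & tb != "*"
  c(aa = 100 * mean(ta[keep] == tb[keep]), nt = nt)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One row of a canonical hit data.frame.
.hit_row <- function(query, subject, pident, len, evalue, bitscore,
                     qlen = NA, slen = NA, staxid = NA,
                     search_type = "protein") {
  data.frame(query_id = query, subject_id = subject, pct_identity = pident,
             aligned_length = len, mismatch = round(len * (1 - pident / 100)),
             gapopen = 0, qstart = 1, qend = len, sstart = 1, send = len,
             evalue = evalue, bitscore = bitscore, query_length = qlen,
             subject_length = slen, subject_taxon_id = as.numeric(staxid),
             query_coverage = pmin(1, len / qlen),
             subject_coverage = pmin(1, len / slen),
             search_type = search_type, stringsAsFactors = FALSE)
}

#' Simulate library metadata
#'
#' Libraries are assigned a species (the first three codes are made
#' dominant, mirroring field prevalence), a location and a year; non-rRNA
#' read totals vary around `reads_per_library`.
#'
#' @param config a [sim_config()].
#' @return library metadata data.frame (see [read_library_metadata()]).
#' @export
simulate_libraries <- function(config) {
  set.seed(config$seed + 2L)
  species <- SPECIES_CODES[seq_len(config$n_species)]
  w <- c(5, 5, 5, rep(2, min(5, config$n_species - 3)),
         rep(1, max(0, config$n_species - 8)))
  data.frame(
    library_id = sprintf("L%03d", seq_len(config$n_libraries)),
    species = sample(species, config$n_libraries, replace = TRUE,
                     prob = w / sum(w)),
    location = sample(LOCATION_CODES[seq_len(config$n_locations)],
                      config$n_libraries, replace = TRUE),
    year = sample(config$years, config$n_libraries, replace = TRUE),
    n_nonrrna_reads = round(config$reads_per_library *
                              stats::runif(config$n_libraries, 0.7, 1.3)),
    stringsAsFactors = FALSE)
}

#' Simulate viral contigs, decoys and their hit tables
#'
#' Each planted virus mutates its reference to hit its amino-acid and
#' nucleotide identity targets within one percentage point (verified
#' internally; the planted substitutions contain no indels, so Hamming
#' identity equals global-alignment identity). Emitted hit tables carry
#' identities, e-values, bitscores and coverages consistent with the
#' planted truth. Decoy mosquito-genome contigs (best hit in the host
#' table) and short viral fragments (<= 300 nt) exercise the
#' false-positive and length filters; one virus is detectable only through
#' the RdRp domain search at e-value 1e-3.
#'
#' @param config a [sim_config()].
#' @param references output of [simulate_reference_set()].
#' @param libraries output of [simulate_libraries()].
#' @return list: `contigs` (named character vector of sequences),
#'   `hits_by_db` (list `genbank_viral`, `ictv_vmr`, `rdrp_cdd`),
#'   `host_hits`, `nr_nt_hits`, `nt_hits` (nucleotide search against the
#'   references, used for the novelty nt condition), `truth` (per-contig
#'   ground truth) and `virus_table` (per-virus truth incl. host species).
#' @export
simulate_viral_contigs <- function(config, references, libraries) {
  set.seed(config$seed + 3L)
  n_known <- config$n_known_viruses
  n_novel <- config$n_novel_viruses
  n <- n_known + n_novel
  virus_ids <- sprintf("v%02d", seq_len(n))
  novelty <- c(rep("known", n_known), rep("novel", n_novel))

  # identity targets: always >= 2 points away from the 80/90 thresholds
  aa_t <- ifelse(novelty == "known", stats::runif(n, 85, 98),
                 stats::runif(n, 45, 75))
  nt_max_feasible <- 100 - (100 - aa_t) / 3  # one nt change per aa change
  nt_t <- ifelse(novelty == "known",
                 pmin(stats::runif(n, 92, 97), nt_max_feasible - 0.5),
                 pmin(stats::runif(n, 70, 86), nt_max_feasible - 0.5))
  cov_t <- ifelse(stats::runif(n) < 0.75, stats::runif(n, 0.84, 0.98),
                  stats::runif(n, 0.55, 0.78))

  # host species: dominant species carry most viruses
  by_prev <- names(sort(table(libraries$species), decreasing = TRUE))
  host_species <- by_prev[(seq_len(n) - 1) %% min(6, length(by_prev)) + 1]
  # vertical viruses: two per dominant species (where available)
  vertical <- rep(FALSE, n)
  for (sp in by_prev[1:3]) {
    idx <- which(host_species == sp)
    vertical[idx[seq_len(min(2, length(idx)))]] <- TRUE
  }

  hits_g <- list(); hits_i <- list(); hits_c <- list(); hits_nt <- list()
  contigs <- character(0)
  truth <- list()
  cdd_only <- n_known + 1L  # first novel virus: domain-search evidence only
  for (i in seq_len(n)) {
    ref <- as.character(references[[sprintf("ref_v%02d", i)]])
    mut <- mutate_to_targets(ref, aa_t[i], nt_t[i])
    ids <- .measure_identities(ref, mut)
    if (abs(ids["aa"] - aa_t[i]) > 1 || abs(ids["nt"] - nt_t[i]) > 1)
      stopf("virus %s missed its identity target", virus_ids[i])
    cid <- sprintf("contig_%s", virus_ids[i])
    contigs[cid] <- mut
    slen_aa <- (nchar(ref) - 3) / 3
    qlen_aa <- (nchar(mut) - 3) / 3
    alen <- round(cov_t[i] * slen_aa)
    bits <- round(2 * alen * ids["aa"] / 100)
    if (i == cdd_only) {
      hits_c[[cid]] <- .hit_row(cid, "RdRp_cdd_pssm", ids["aa"], alen,
                                1e-3, bits, qlen_aa, slen_aa, 4)
    } else {
      hits_g[[cid]] <- .hit_row(cid, sprintf("ref_v%02d", i), ids["aa"],
                                alen, 1e-20, bits, qlen_aa, slen_aa, 4)
      if (stats::runif(1) < 0.5)
        hits_i[[cid]] <- .hit_row(cid, sprintf("ictv_v%02d", i), ids["aa"],
                                  alen, 1e-15, bits - 5, qlen_aa, slen_aa, 4)
      if (stats::runif(1) < 0.3)
        hits_c[[cid]] <- .hit_row(cid, "RdRp_cdd_pssm", ids["aa"],
                                  round(alen * 0.6), 1e-4,
                                  round(bits * 0.5), qlen_aa, slen_aa, 4)
    }
    hits_nt[[cid]] <- .hit_row(cid, sprintf("ref_v%02d", i), ids["nt"],
                               round(cov_t[i] * nchar(ref)), 1e-20,
                               round(1.5 * cov_t[i] * nchar(ref)),
                               nchar(mut), nchar(ref), 4,
                               search_type = "nucleotide")
    truth[[cid]] <- data.frame(
      contig_id = cid, class = "virus", virus_id = virus_ids[i],
      species = host_species[i], novelty = novelty[i],
      aa_identity = unname(ids["aa"]), nt_identity = unname(ids["nt"]),
      ref_coverage_aa = cov_t[i], vertical = vertical[i],
      stringsAsFactors = FALSE)
  }

  # decoy host contigs: weak viral hit, dominant Culicidae-genome hit
  host_rows <- list()
  for (d in 1:4) {
    cid <- sprintf("contig_host%02d", d)
    contigs[cid] <- .random_dna(900)
    hits_g[[cid]] <- .hit_row(cid, "ref_v01", 32, 120, 1e-6, 60,
                              300, 400, 4)
    host_rows[[cid]] <- .hit_row(cid, sprintf("culicidae_scaffold_%d", d),
                                 98, 880, 1e-80, 600, 900, 5000,
                                 sample(ARTHROPOD_SPECIES, 1),
                                 search_type = "nucleotide")
    truth[[cid]] <- data.frame(
      contig_id = cid, class = "host_decoy", virus_id = NA, species = NA,
      novelty = NA, aa_identity = NA, nt_identity = NA,
      ref_coverage_aa = NA, vertical = NA, stringsAsFactors = FALSE)
  }
  # short viral fragments: strong hit but <= 300 nt, dropped by length rule
  for (s in 1:2) {
    cid <- sprintf("contig_short%02d", s)
    contigs[cid] <- substr(contigs[[sprintf("contig_v%02d", s)]], 1, 280)
    hits_g[[cid]] <- .hit_row(cid, sprintf("ref_v%02d", s), 95, 90,
                              1e-10, 170, 93, 400, 4)
    truth[[cid]] <- data.frame(
      contig_id = cid, class = "short_viral", virus_id = NA, species = NA,
      novelty = NA, aa_identity = NA, nt_identity = NA,
      ref_coverage_aa = NA, vertical = NA, stringsAsFactors = FALSE)
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else
    hit_frame(NULL, "protein")
  vt <- data.frame(virus_id = virus_ids, novelty = novelty,
                   aa_target = aa_t, nt_target = nt_t, coverage = cov_t,
                   species = host_species, vertical = vertical,
                   stringsAsFactors = FALSE)
  list(contigs = contigs,
       hits_by_db = list(genbank_viral = bind(hits_g),
                         ictv_vmr = bind(hits_i),
                         rdrp_cdd = bind(hits_c)),
       host_hits = bind(host_rows),
       nr_nt_hits = hit_frame(NULL, "protein"),
       nt_hits = bind(hits_nt),
       truth = do.call(rbind, unname(truth)),
       virus_table = vt)
}

#' Simulate mapping summaries with species-specific virome structure
#'
#' Each virus is present only in libraries of its host species: vertical
#' viruses in every library of the species (hence all sampled years),
#' environment-derived viruses in a year-location mosaic restricted to at
#' most two years. Mapped reads are negative-binomial around the expected
#' RPM times depth; truly present cells get high reference coverage, and a
#' small fraction of absent cells receive stray reads at low coverage.
#'
#' @param config a [sim_config()].
#' @param virus_table `virus_table` from [simulate_viral_contigs()].
#' @param libraries output of [simulate_libraries()].
#' @return list: `mapping` (mapping-summary data.frame), `presence`
#'   (planted OTU x library logical truth), `rpm_expected` (per virus).
#' @export
simulate_abundances <- function(config, virus_table, libraries) {
  set.seed(config$seed + 4L)
  n <- nrow(virus_table)
  rpm_exp <- exp(stats::runif(n, log(config$rpm_range[1]),
                              log(config$rpm_range[2])))
  libs <- libraries$library_id
  presence <- matrix(FALSE, n, length(libs),
                     dimnames = list(virus_table$virus_id, libs))
  for (i in seq_len(n)) {
    sp_libs <- libraries[libraries$species == virus_table$species[i], ]
    if (!nrow(sp_libs)) next
    if (virus_table$vertical[i]) {
      presence[i, sp_libs$library_id] <- TRUE
    } else {
      yrs <- sample(config$years, sample(1:2, 1))
      cell <- sp_libs[sp_libs$year %in% yrs, ]
      if (!nrow(cell)) cell <- sp_libs[1, , drop = FALSE]
      on <- stats::runif(nrow(cell)) < 0.6
      if (!any(on)) on[sample.int(nrow(cell), 1)] <- TRUE
      presence[i, cell$library_id[on]] <- TRUE
    }
  }
  depth <- stats::setNames(libraries$n_nonrrna_reads, libs)
  rows <- list()
  size <- 1 / config$nb_dispersion
  for (i in seq_len(n)) {
    for (l in libs[presence[i, ]]) {
      mu <- rpm_exp[i] * depth[[l]] / 1e6
      rows[[length(rows) + 1L]] <- data.frame(
        otu_id = virus_table$virus_id[i], library_id = l,
        mapped_reads = max(5, stats::rnbinom(1, mu = mu, size = size)),
        ref_coverage = stats::runif(1, 0.65, 1),
        stringsAsFactors = FALSE)
    }
    absent <- libs[!presence[i, ]]
    stray <- absent[stats::runif(length(absent)) < config$spurious_rate]
    for (l in stray)
      rows[[length(rows) + 1L]] <- data.frame(
        otu_id = virus_table$virus_id[i], library_id = l,
        mapped_reads = sample(1:3, 1),
        ref_coverage = stats::runif(1, 0, 0.45),
        stringsAsFactors = FALSE)
  }
  list(mapping = do.call(rbind, rows), presence = presence,
       rpm_expected = stats::setNames(rpm_exp, virus_table$virus_id))
}

#' Simulate food-source hit tables with planted associations
#'
#' Per library, food families are present with species-dependent base
#' probabilities; planted (virus, family) co-occurrences raise the family
#' probability to `strength` in libraries containing the virus. Present
#' families emit one or two contigs with hits passing all three filter
#' criteria; a known fraction of contigs carries a planted equal-bitscore
#' tie between two species of the family (resolved to the family by LCA).
#' Decoy hits (arthropod subjects, short fragments, low coverage, weak
#' e-values) and fungal contigs exercise the exclusion rules.
#'
#' @param config a [sim_config()].
#' @param libraries output of [simulate_libraries()].
#' @param virus_presence planted OTU x library presence matrix (from
#'   [simulate_abundances()]).
#' @return list: `hits` (nucleotide hit data.frame), `contig_lengths`,
#'   `contig_library` (named vector), `truth` (per-contig planted family,
#'   `NA` for decoys), `family_presence` (planted family x library logical
#'   matrix).
#' @export
simulate_food_hits <- function(config, libraries, virus_presence) {
  set.seed(config$seed + 5L)
  fams <- c(METAZOA_FAMILIES, PLANT_FAMILIES)
  libs <- libraries$library_id
  species <- unique(libraries$species)
  base_p <- matrix(stats::runif(length(fams) * length(species), 0.05, 0.45),
                   length(fams), length(species),
                   dimnames = list(names(fams), species))
  fam_presence <- matrix(FALSE, length(fams), length(libs),
                         dimnames = list(names(fams), libs))
  planted <- config$planted_cooccurrences
  for (j in seq_along(libs)) {
    sp <- libraries$species[j]
    p <- base_p[, sp]
    if (nrow(planted)) for (r in seq_len(nrow(planted))) {
      v <- planted$virus[r]
      if (v %in% rownames(virus_presence))
        p[planted$family[r]] <- if (virus_presence[v, libs[j]])
          planted$strength[r] else 0.05
    }
    fam_presence[, j] <- stats::runif(length(fams)) < p
  }

  rows <- list(); lens <- numeric(0); libmap <- character(0)
  truth <- list()
  cnt <- 0L
  add_contig <- function(lib, fam, tie) {
    cnt <<- cnt + 1L
    cid <- sprintf("food_%05d", cnt)
    alen <- sample(250:600, 1)
    qlen <- round(alen / stats::runif(1, 0.82, 0.98))
    bits <- round(1.8 * alen)
    spp <- fams[[fam]]
    if (tie && length(spp) >= 2) {
      pick <- sample(spp, 2)
      rows[[length(rows) + 1L]] <<- .hit_row(cid, paste0("acc_", pick[1]),
        stats::runif(1, 90, 99), alen, 1e-8, bits, qlen, alen + 50,
        pick[1], search_type = "nucleotide")
      rows[[length(rows) + 1L]] <<- .hit_row(cid, paste0("acc_", pick[2]),
        stats::runif(1, 90, 99), alen, 1e-8, bits, qlen, alen + 50,
        pick[2], search_type = "nucleotide")
    } else {
      pick <- sample(spp, 1)
      rows[[length(rows) + 1L]] <<- .hit_row(cid, paste0("acc_", pick),
        stats::runif(1, 90, 99), alen, 1e-8, bits, qlen, alen + 50,
        pick, search_type = "nucleotide")
      if (stats::runif(1) < 0.3)  # secondary, clearly lower bitscore
        rows[[length(rows) + 1L]] <<- .hit_row(cid, "acc_other",
          stats::runif(1, 70, 85), alen, 1e-6, bits - 40, qlen, alen + 50,
          sample(unlist(fams), 1), search_type = "nucleotide")
    }
    lens[cid] <<- qlen
    libmap[cid] <<- lib
    truth[[cid]] <<- data.frame(contig_id = cid, library_id = lib,
                                family = fam, tie = tie,
                                stringsAsFactors = FALSE)
  }
  for (j in seq_along(libs)) {
    for (fam in names(fams)[fam_presence[, j]]) {
      n_contigs <- sample(1:2, 1)
      for (z in seq_len(n_contigs))
        add_contig(libs[j], fam, tie = stats::runif(1) < 0.25)
    }
  }
  # decoys: one of each failure mode in a handful of libraries
  decoy_libs <- libs[seq_len(min(5, length(libs)))]
  for (lib in decoy_libs) {
    mk <- function(suffix, subject, pident, alen, qlen, evalue, staxid) {
      cnt <<- cnt + 1L
      cid <- sprintf("decoy_%05d_%s", cnt, suffix)
      rows[[length(rows) + 1L]] <<- .hit_row(cid, subject, pident, alen,
        evalue, round(1.8 * alen), qlen, alen + 50, staxid,
        search_type = "nucleotide")
      lens[cid] <<- qlen
      libmap[cid] <<- lib
      truth[[cid]] <<- data.frame(contig_id = cid, library_id = lib,
                                  family = NA_character_, tie = FALSE,
                                  stringsAsFactors = FALSE)
    }
    mk("arth", "acc_mosquito", 99, 500, 520, 1e-30,
       sample(ARTHROPOD_SPECIES, 1))               # arthropod exclusion
    mk("short", "acc_60", 95, 150, 160, 1e-9, "60")  # fragment <= 200
    mk("lowcov", "acc_62", 95, 300, 600, 1e-9, "62") # coverage <= 0.8
    mk("weak", "acc_64", 92, 400, 430, 1e-4, "64")   # e-value > 1e-5
    mk("fungus", "acc_87", 97, 450, 470, 1e-20, FUNGAL_SPECIES)
  }
  list(hits = do.call(rbind, unname(rows)), contig_lengths = lens,
       contig_library = libmap, truth = do.call(rbind, unname(truth)),
       family_presence = fam_presence)
}

#' Simulate a complete dataset with ground truth
#'
#' Runs every generator stage in sequence. Identical configurations give
#' byte-identical outputs (each stage reseeds deterministically from
#' `config$seed`).
#'
#' @param config a [sim_config()].
#' @return list with `config`, `taxonomy`, `libraries`, `references`,
#'   `viral` (contigs/hit tables/truth), `abundance` (mapping + presence
#'   truth), `food` (hits + truth).
#' @export
simulate_dataset <- function(config = sim_config()) {
  taxonomy <- fixture_taxonomy()
  refs <- simulate_reference_set(config)
  libraries <- simulate_libraries(config)
  viral <- simulate_viral_contigs(config, refs, libraries)
  abundance <- simulate_abundances(config, viral$virus_table, libraries)
  food <- simulate_food_hits(config, libraries, abundance$presence)
  list(config = config, taxonomy = taxonomy, libraries = libraries,
       references = refs, viral = viral, abundance = abundance,
       food = food)
}

#' Validate internal consistency of a simulated dataset
#'
#' Asserts that every emitted record is derivable from the ground truth:
#' planted identities match the hit tables, planted presence matches the
#' mapping summaries (given the expressed-call rule), and every food hit
#' belongs to a truth contig.
#'
#' @param sim output of [simulate_dataset()].
#' @return `TRUE` invisibly; stops on any inconsistency.
#' @export
validate_simulation <- function(sim) {
  vt <- sim$viral$truth[sim$viral$truth$class == "virus", ]
  g <- sim$viral$hits_by_db$genbank_viral
  for (i in seq_len(nrow(vt))) {
    cid <- vt$contig_id[i]
    h <- g[g$query_id == cid, ]
    if (nrow(h) && abs(h$pct_identity[1] - vt$aa_identity[i]) > 1e-9)
      stopf("hit table identity disagrees with truth for %s", cid)
  }
  m <- sim$abundance$mapping
  expressed <- m[call_expressed(m$ref_coverage) & m$mapped_reads > 0, ]
  for (r in seq_len(nrow(expressed)))
    if (!sim$abundance$presence[expressed$otu_id[r],
                                expressed$library_id[r]])
      stopf("expressed cell (%s, %s) not in planted presence",
            expressed$otu_id[r], expressed$library_id[r])
  if (!all(sim$food$hits$query_id %in% sim$food$truth$contig_id))
    stopf("food hit without truth record")
  invisible(TRUE)
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the analysis modules read: contig and
#' reference FASTA, hit tables, library metadata, mapping summaries,
#' taxonomy and a ground-truth table.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(sim$references, p("references.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$viral$contigs), p("contigs.fasta"))
  for (db in names(sim$viral$hits_by_db))
    write_hit_table(sim$viral$hits_by_db[[db]],
                    p(sprintf("hits_%s.tsv", db)))
  write_hit_table(sim$viral$host_hits, p("hits_host.tsv"))
  write_hit_table(sim$viral$nt_hits, p("hits_nt.tsv"))
  write_hit_table(sim$food$hits, p("hits_food.tsv"))
  write_library_metadata(sim$libraries, p("libraries.tsv"))
  write_mapping_summary(sim$abundance$mapping, p("mapping.tsv"))
  write_taxonomy(sim$taxonomy, p("taxonomy.tsv"))
  write_commented_tsv(sim$viral$truth, p("ground_truth_contigs.tsv"))
  write_commented_tsv(sim$food$truth, p("ground_truth_food.tsv"))
  invisible(dir)
}
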