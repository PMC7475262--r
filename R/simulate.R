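## Synthetic multi-strain studies with a full ground-truth table, so every
## pipeline stage is testable without external data. All randomness flows
## from a single seed.

rareDyads <- c("YR", "YY", "YQ", "HP", "HG", "YC", "CY", "YG")

defaultDyadDistribution <- function() {
  p <- c(HC = 0.56, YS = 0.27, YN = 0.09,
         stats::setNames(rep(0.08 / length(rareDyads), length(rareDyads)),
                         rareDyads))
  p / sum(p)
}

defaultPocketTemplates <- function() {
  labs <- c("HC", "YS", "YN", rareDyads, "YH")
  out <- lapply(labs, function(lab) {
    h <- substr(lab, 1, 1); c <- substr(lab, 2, 2)
    switch(lab,
      HC = c(h = "FSGHG", c = "DTCHS"),
      YS = c(h = "FSGYG", c = "DCSYN"),
      YN = c(h = "FSGYG", c = "DSNRS"),
      c(h = paste0("FSG", h, "G"), c = paste0("DT", c, "HS")))
  })
  stats::setNames(out, labs)
}

#' Default simulation configuration
#'
#' The defaults emulate the shape of a cyanobacterial orthocaspase survey:
#' 30 strains in equal morphotype thirds; proteome sizes of 5000-7500
#' proteins; per-strain planted OCA counts Poisson at morphotype-specific
#' rates of 0.066, 0.065 and 0.026 OCAs per 100 proteins (heterocytous,
#' filamentous, unicellular), which yields about 98 planted OCAs in
#' expectation; a dyad-label distribution of 56\% HC, 27\% YS, 9\% YN and
#' eight rare dyads sharing the remaining 8\%; pocket 5-mers drawn from
#' per-label templates whose pooled consensus reads FSG(H/Y)G-style
#' patterns; accessory-domain motifs at the observed per-OCA inclusion
#' frequencies (WD40 9\%, AAA_16 6\%, NACHT 4\%, plus DUF domains and
#' pentapeptide repeats); and a 21-residue hydrophobic transmembrane
#' stretch in 25/98 of OCAs, N-terminal to the p20 in 3/25 of those.
#' Only a capped subsample of background proteins per strain is emitted
#' (the nominal proteome size remains the abundance denominator).
#'
#' @return a named list; override entries via [simulationConfig()].
#' @export
defaultSimulationConfig <- function() {
  list(
    n_strains = 30L,
    morphotype_mix = c(unicellular = 1 / 3, filamentous = 1 / 3,
                       heterocytous = 1 / 3),
    habitat_probs = c(freshwater = 0.45, marine = 0.05, terrestrial = 0.30,
                      symbiotic = 0.10, other = 0.10),
    proteome_size_range = c(5000L, 7500L),
    n_background = 120L,
    background_length_range = c(100L, 400L),
    oca_rate = c(unicellular = 0.026, filamentous = 0.065,
                 heterocytous = 0.066),
    dyad_distribution = defaultDyadDistribution(),
    pocket_templates = defaultPocketTemplates(),
    p20_template = P20_TEMPLATE,
    h_pos = P20_TEMPLATE_H_POS,
    c_pos = P20_TEMPLATE_C_POS,
    accessory_motifs = ACCESSORY_MOTIFS,
    accessory_probs = c(WD40 = 0.09, AAA_16 = 0.06, NACHT = 0.04,
                        DUF4384 = 0.04, DUF2808 = 0.03, DUF2610 = 0.02,
                        Pentapeptide = 0.03),
    tm_probability = 25 / 98,
    tm_n_side_probability = 3 / 25,
    background_composition = PROTEOME_COMPOSITION,
    point_mutation_rate = 0,
    seed = 1L)
}

#' Build a simulation configuration
#'
#' Starts from [defaultSimulationConfig()] and overrides named entries.
#'
#' @param ... entries to override (e.g. `n_strains = 5`,
#'   `point_mutation_rate = 0.05`).
#' @return validated configuration list.
#' @export
simulationConfig <- function(...) {
  cfg <- defaultSimulationConfig()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(
    abs(sum(cfg$morphotype_mix) - 1) < 1e-8,
    abs(sum(cfg$habitat_probs) - 1) < 1e-8,
    abs(sum(cfg$dyad_distribution) - 1) < 1e-8,
    all(names(cfg$dyad_distribution) %in% names(cfg$pocket_templates)),
    cfg$point_mutation_rate >= 0, cfg$point_mutation_rate < 1)
  ## pocket centres must carry the label residues
  for (lab in names(cfg$dyad_distribution)) {
    pk <- cfg$pocket_templates[[lab]]
    if (substr(pk[["h"]], 4, 4) != substr(lab, 1, 1) ||
        substr(pk[["c"]], 3, 3) != substr(lab, 2, 2))
      stop("pocket template inconsistent with dyad label ", lab)
  }
  cfg
}

#' Generate one background protein
#'
#' Residues are drawn i.i.d. from the given composition. With
#' `rejectTm = TRUE` (automatic for hydrophilic-only compositions) the draw
#' is rejected until no hydropathy window reaches the TM threshold, so the
#' protein is guaranteed free of spurious transmembrane calls.
#'
#' @param length protein length (> 0).
#' @param composition named residue-frequency vector; default
#'   proteome-like. `hydrophilicComposition()` gives a composition with no
#'   hydrophobic residues.
#' @param rejectTm logical; resample until [predictTM()] finds nothing.
#' @return amino-acid string.
#' @export
generateBackgroundProtein <- function(length,
                                      composition = PROTEOME_COMPOSITION,
                                      rejectTm = FALSE) {
  stopifnot(length > 0)
  for (try in 1:100) {
    s <- paste(sample(names(composition), length, replace = TRUE,
                      prob = composition), collapse = "")
    if (!rejectTm || nrow(predictTM(s)) == 0) return(s)
  }
  stop("could not draw a TM-free background protein in 100 tries")
}

#' Hydrophilic-only residue composition
#'
#' @return named frequency vector over residues with negative
#'   Kyte-Doolittle hydropathy only.
#' @export
hydrophilicComposition <- function() HYDROPHILIC_COMPOSITION

mutateSequence <- function(chars, rate, protect) {
  if (rate <= 0) return(chars)
  idx <- setdiff(which(stats::runif(length(chars)) < rate), protect)
  if (length(idx))
    chars[idx] <- sample(AMINO_ACIDS, length(idx), replace = TRUE)
  chars
}

#' Plant a synthetic orthocaspase
#'
#' Copies the p20 template, overwrites the two specificity-pocket windows
#' with the label's pocket 5-mers, mutates the remaining template residues
#' i.i.d. at `mutationRate`, and assembles the full protein: an optional
#' 21-residue hydrophobic transmembrane stretch (N- or C-terminal of the
#' p20) and accessory-domain motifs appended C-terminally, all joined by
#' short linkers. Every element's coordinates are recorded in the returned
#' truth row.
#'
#' @param dyadLabel two-letter dyad label; must be consistent with the
#'   pocket centres (H residue at pocket unit 4, C residue at unit 3).
#' @param pockets named character vector `c(h = , c = )` of 5-mers;
#'   defaults to the label's template from the configuration.
#' @param accessory character vector of accessory domain names to append.
#' @param tm logical, plant a transmembrane stretch.
#' @param tmSide `"N"` or `"C"` relative to the p20.
#' @param mutationRate per-residue substitution probability outside the
#'   pocket windows.
#' @param config simulation configuration (template, motifs).
#' @return list with `sequence` and `truth` (a one-row data.frame with the
#'   p20 span, dyad positions/label, pockets, accessory string, TM span).
#' @export
plantOca <- function(dyadLabel, pockets = NULL, accessory = character(),
                     tm = FALSE, tmSide = "C", mutationRate = 0,
                     config = defaultSimulationConfig()) {
  if (is.null(pockets)) {
    pockets <- config$pocket_templates[[dyadLabel]]
    if (is.null(pockets)) stop("no pocket template for dyad ", dyadLabel)
  }
  stopifnot(nchar(pockets[["h"]]) == 5, nchar(pockets[["c"]]) == 5)
  if (substr(pockets[["h"]], 4, 4) != substr(dyadLabel, 1, 1) ||
      substr(pockets[["c"]], 3, 3) != substr(dyadLabel, 2, 2))
    stop("pockets inconsistent with dyad label ", dyadLabel)
  hPos <- config$h_pos; cPos <- config$c_pos
  chars <- strsplit(config$p20_template, "")[[1]]
  hWin <- (hPos - 3):(hPos + 1)
  cWin <- (cPos - 2):(cPos + 2)
  chars[hWin] <- strsplit(pockets[["h"]], "")[[1]]
  chars[cWin] <- strsplit(pockets[["c"]], "")[[1]]
  chars <- mutateSequence(chars, mutationRate, protect = c(hWin, cWin))
  core <- paste(chars, collapse = "")

  parts <- character(); elements <- list()
  offset <- 0L
  addPart <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    start <- offset + 1L
    offset <<- offset + nchar(s)
    c(start = start, end = offset)
  }
  tmSpan <- c(start = NA_integer_, end = NA_integer_)
  if (tm && tmSide == "N") {
    tmSpan <- addPart(TM_STRETCH)
    addPart(LINKER)
  }
  p20Span <- addPart(core)
  if (tm && tmSide == "C") {
    addPart(LINKER)
    tmSpan <- addPart(TM_STRETCH)
  }
  accRows <- list()
  for (nm in accessory) {
    motif <- config$accessory_motifs[[nm]]
    if (is.null(motif)) stop("no motif defined for accessory domain ", nm)
    addPart(LINKER)
    accRows[[nm]] <- addPart(motif)
  }
  truth <- data.frame(
    dyad_label = dyadLabel,
    p20_start = unname(p20Span["start"]), p20_end = unname(p20Span["end"]),
    h_pos = unname(p20Span["start"]) + hPos - 1L,
    c_pos = unname(p20Span["start"]) + cPos - 1L,
    h_pocket = pockets[["h"]], c_pocket = pockets[["c"]],
    accessory = paste(accessory, collapse = ","),
    tm_start = unname(tmSpan["start"]), tm_end = unname(tmSpan["end"]),
    stringsAsFactors = FALSE)
  list(sequence = paste(parts, collapse = ""), truth = truth,
       accessory_spans = accRows)
}

#' Generate a full synthetic study
#'
#' Per strain: morphotype and habitat drawn from the configured mixes, a
#' nominal proteome size drawn from `proteome_size_range`, a planted OCA
#' count drawn from Poisson with mean `oca_rate[morphotype] *
#' proteome_size / 100`, dyad labels from `dyad_distribution`, accessory
#' domains and transmembrane stretches at their inclusion probabilities,
#' plus `n_background` emitted background proteins. Fully reproducible
#' from the seed.
#'
#' @param config configuration from [simulationConfig()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `proteins` (strain_id, protein_id, sequence),
#'   `metadata` (strain table), `annotations` (accessory-domain TSV rows
#'   emitted from truth), `truth_oca` (per planted OCA) and
#'   `truth_strains` (planted counts per strain).
#' @export
generateStudy <- function(config = defaultSimulationConfig(),
                          seed = config$seed) {
  set.seed(as.integer(seed))
  proteins <- list(); meta <- list(); truth <- list(); ann <- list()
  for (s in seq_len(config$n_strains)) {
    sid <- sprintf("S%02d", s)
    morph <- sample(names(config$morphotype_mix), 1,
                    prob = config$morphotype_mix)
    hab <- sample(names(config$habitat_probs), 1,
                  prob = config$habitat_probs)
    psize <- sample(config$proteome_size_range[1]:
                      config$proteome_size_range[2], 1)
    nOca <- stats::rpois(1, config$oca_rate[[morph]] * psize / 100)
    strainRows <- list()
    for (k in seq_len(nOca)) {
      pid <- sprintf("%s_oca%02d", sid, k)
      lab <- sample(names(config$dyad_distribution), 1,
                    prob = config$dyad_distribution)
      acc <- names(config$accessory_probs)[
        stats::runif(length(config$accessory_probs)) <
          config$accessory_probs]
      tm <- stats::runif(1) < config$tm_probability
      tmSide <- if (tm && stats::runif(1) < config$tm_n_side_probability)
        "N" else "C"
      oca <- plantOca(lab, accessory = acc, tm = tm, tmSide = tmSide,
                      mutationRate = config$point_mutation_rate,
                      config = config)
      strainRows[[pid]] <- oca$sequence
      tr <- cbind(data.frame(strain_id = sid, protein_id = pid,
                             stringsAsFactors = FALSE), oca$truth)
      truth[[pid]] <- tr
      for (nm in names(oca$accessory_spans)) {
        sp <- oca$accessory_spans[[nm]]
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = pid, domain_name = nm,
          start = unname(sp["start"]), end = unname(sp["end"]),
          score = NA_real_, stringsAsFactors = FALSE)
      }
    }
    for (k in seq_len(config$n_background)) {
      pid <- sprintf("%s_bg%04d", sid, k)
      len <- sample(config$background_length_range[1]:
                      config$background_length_range[2], 1)
      strainRows[[pid]] <- generateBackgroundProtein(
        len, config$background_composition)
    }
    proteins[[sid]] <- data.frame(
      strain_id = sid, protein_id = names(strainRows),
      sequence = unlist(strainRows, use.names = FALSE),
      stringsAsFactors = FALSE)
    meta[[sid]] <- data.frame(
      strain_id = sid, morphotype = morph, habitat = hab,
      proteome_size = psize, n_planted = nOca, stringsAsFactors = FALSE)
  }
  truthOca <- if (length(truth)) do.call(rbind, truth) else
    data.frame(strain_id = character(), protein_id = character(),
               dyad_label = character(), p20_start = integer(),
               p20_end = integer(), h_pos = integer(), c_pos = integer(),
               h_pocket = character(), c_pocket = character(),
               accessory = character(), tm_start = integer(),
               tm_end = integer(), stringsAsFactors = FALSE)
  rownames(truthOca) <- NULL
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(protein_id = character(), domain_name = character(),
               start = integer(), end = integer(), score = numeric(),
               stringsAsFactors = FALSE)
  list(proteins = do.call(rbind, c(proteins, make.row.names = FALSE)),
       metadata = metadata[c("strain_id", "morphotype", "habitat",
                             "proteome_size")],
       annotations = annotations,
       truth_oca = truthOca,
       truth_strains = metadata,
       config = config, seed = as.integer(seed))
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' One FASTA per strain, a metadata TSV, an annotation TSV and the truth
#' table TSV.
#'
#' @param study result of [generateStudy()].
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sid in unique(study$proteins$strain_id)) {
    p <- file.path(dir, paste0(sid, ".faa"))
    writeProteomeFasta(study$proteins[study$proteins$strain_id == sid, ], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "metadata.tsv")
  writeTsv(study$metadata, p); paths <- c(paths, p)
  p <- file.path(dir, "annotations.tsv")
  writeTsv(study$annotations[c("protein_id", "domain_name", "start", "end",
                               "score")], p)
  paths <- c(paths, p)
  p <- file.path(dir, "truth_oca.tsv")
  writeTsv(study$truth_oca, p); paths <- c(paths, p)
  invisible(paths)
}

#' Simulate divergent dyad groups for clade analysis
#'
#' Generates p20-like proteins in labelled groups (e.g. YS and YN), each
#' group derived from its own diverged copy of the template
#' (`groupDivergence` substitutions per residue, drawn once per group) with
#' small within-group variation (`withinRate`), plus a heavily diverged
#' outgroup sequence. Between-group divergence far exceeds within-group
#' divergence, so a correct tree shows each group as a clade.
#'
#' @param nPerGroup named integer vector, group label -> number of
#'   proteins (labels must have pocket templates).
#' @param groupDivergence per-residue substitution rate applied once to
#'   each group's template copy; default 0.25.
#' @param withinRate per-residue substitution rate per protein; default
#'   0.03.
#' @param seed integer seed.
#' @param config simulation configuration.
#' @return list with `proteins` (single pseudo-strain), `labels` (named
#'   vector protein id -> group label) and `outgroup_id`.
#' @export
simulateDyadGroups <- function(nPerGroup, groupDivergence = 0.25,
                               withinRate = 0.03, seed = 1,
                               config = defaultSimulationConfig()) {
  set.seed(as.integer(seed))
  hWin <- (config$h_pos - 3):(config$h_pos + 1)
  cWin <- (config$c_pos - 2):(config$c_pos + 2)
  protect <- c(hWin, cWin)
  rows <- list(); labels <- character()
  for (lab in names(nPerGroup)) {
    base <- strsplit(config$p20_template, "")[[1]]
    idx <- setdiff(which(stats::runif(length(base)) < groupDivergence),
                   protect)
    base[idx] <- sample(AMINO_ACIDS, length(idx), replace = TRUE)
    groupTemplate <- paste(base, collapse = "")
    groupConfig <- config
    groupConfig$p20_template <- groupTemplate
    for (k in seq_len(nPerGroup[[lab]])) {
      pid <- sprintf("%s_%02d", lab, k)
      oca <- plantOca(lab, mutationRate = withinRate, config = groupConfig)
      rows[[pid]] <- oca$sequence
      labels[pid] <- lab
    }
  }
  og <- strsplit(config$p20_template, "")[[1]]
  idx <- which(stats::runif(length(og)) < 0.35)
  og[idx] <- sample(AMINO_ACIDS, length(idx), replace = TRUE)
  rows[["outgroup"]] <- paste(og, collapse = "")
  list(proteins = data.frame(strain_id = "sim", protein_id = names(rows),
                             sequence = unlist(rows, use.names = FALSE),
                             stringsAsFactors = FALSE),
       labels = labels, outgroup_id = "outgroup")
}
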