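## End-to-end orchestration: scan -> classify -> architecture -> abundance
## -> phylogeny, with self-consistency checks and a single report object.

#' Run the full orthocaspase survey
#'
#' Executes the pipeline stages in order on a protein table: builds the
#' p20 profile from a seed alignment, calibrates the reporting threshold on
#' residue-shuffled background proteins, scans every protein, classifies
#' catalytic dyads and extracts specificity pockets, predicts transmembrane
#' segments and assembles domain architectures for every hit protein,
#' computes per-strain and per-group abundance statistics, substitution
#' tallies and pocket consensus patterns, and builds the dyad-labelled
#' neighbour-joining tree with its clade-purity report. Report
#' self-consistency checks run automatically and fail hard.
#'
#' The reporting threshold is the empirical `thresholdQuantile` of best-hit
#' scores on `nBackground` shuffled proteins, floored at `thresholdFloor`
#' times the profile self-score (the floor suppresses the residual ~0.1\%
#' of background proteins that clear a pure 0.999 quantile).
#'
#' @param proteins protein table (`strain_id`, `protein_id`, `sequence`).
#' @param metadata strain metadata table.
#' @param annotations optional accessory-domain annotation table.
#' @param seed integer seed driving threshold calibration.
#' @param seedAlignment a [SeedAlignment-class]; default the bundled one.
#' @param thresholdQuantile background quantile for the score threshold.
#' @param thresholdFloor floor as a fraction of the profile self-score.
#' @param nBackground number of shuffled background proteins.
#' @param outgroup optional one-row protein table used to root the tree.
#' @param minCladeSize minimum reported pure-clade size.
#' @return a study report: list with `calls`, `strain_summaries`,
#'   `group_means`, `partition`, `habitat_table`, `tallies`, `consensus`,
#'   `architectures`, `architectures_table`, `domain_frequency`,
#'   `cooccurrence_nacht_wd40`, `tree`, `tree_labels`, `clades`, `run`.
#' @export
runStudy <- function(proteins, metadata, annotations = NULL, seed = 1,
                     seedAlignment = exampleSeedAlignment(),
                     thresholdQuantile = 0.999, thresholdFloor = 0.25,
                     nBackground = 1000, outgroup = NULL,
                     minCladeSize = 3L) {
  stopifnot(nrow(proteins) > 0, nrow(metadata) > 0)
  profile <- buildProfile(seedAlignment)
  bg <- makeShuffledBackground(proteins, n = nBackground, seed = seed)
  q <- calibrateThreshold(profile, bg, thresholdQuantile)
  thr <- max(q, thresholdFloor * selfScore(profile))
  scoreThreshold(profile) <- thr

  scanSet <- proteins
  if (!is.null(outgroup)) scanSet <- rbind(scanSet, outgroup)
  hits <- scanProteins(profile, scanSet)
  ogId <- if (!is.null(outgroup)) outgroup$protein_id else character()
  studyHits <- hits[!hits$protein_id %in% ogId, , drop = FALSE]
  calls <- callActiveSites(profile, studyHits, proteins)

  ## architectures for every hit-carrying protein
  archs <- list(); topo <- list()
  hitIds <- unique(studyHits$protein_id)
  for (pid in hitIds) {
    ph <- studyHits[studyHits$protein_id == pid, , drop = FALSE]
    seqc <- proteins$sequence[match(pid, proteins$protein_id)]
    ann <- if (!is.null(annotations))
      annotations[annotations$protein_id == pid, , drop = FALSE] else NULL
    tms <- predictTM(seqc)
    a <- buildArchitecture(pid, ph, ann, tms, nchar(seqc))
    archs[[pid]] <- a
    topo[[pid]] <- classifyTopology(a)
  }
  archTable <- if (length(archs)) data.frame(
    protein_id = hitIds,
    architecture_string = vapply(archs, architectureString, ""),
    unique_domains = vapply(archs, function(a)
      paste(uniqueDomains(a), collapse = ","), ""),
    localization = vapply(topo, `[[`, "", "localization"),
    p20_side = vapply(topo, `[[`, "", "p20_side"),
    n_tm = vapply(topo, `[[`, 0L, "n_tm"),
    multi_p20 = vapply(archs, function(a) a@multiP20, TRUE),
    stringsAsFactors = FALSE, row.names = NULL) else NULL

  summaries <- summarizeStrains(calls, metadata)
  partition <- partitionStrains(summaries)
  tallies <- tallySubstitutions(calls, metadata)
  resolved <- calls[calls$oca_class != "unresolved", , drop = FALSE]
  consensus <- if (nrow(resolved)) list(
    h_pocket = deriveConsensus(resolved$h_pocket)$pattern,
    c_pocket = deriveConsensus(resolved$c_pocket)$pattern) else NULL

  ## phylogeny over resolved single-hit taxa (first hit per protein)
  tree <- NULL; clades <- NULL; treeLabels <- NULL
  taxaHits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  taxaHits <- taxaHits[taxaHits$protein_id %in%
                         c(resolved$protein_id, ogId), , drop = FALSE]
  if (nrow(taxaHits) >= 3) {
    aln <- projectAlignment(taxaHits, scanSet)
    dm <- pDistanceMatrix(aln)
    tree <- njTree(dm)
    treeLabels <- stats::setNames(resolved$dyad_label, resolved$protein_id)
    if (length(ogId) && ogId %in% tree$tip.label)
      tree <- rootWithOutgroup(tree, ogId)
    clades <- pureClades(tree, treeLabels, minSize = minCladeSize,
                         exclude = ogId)
  }

  report <- list(
    calls = calls,
    strain_summaries = summaries,
    group_means = list(
      morphotype = groupMeans(summaries, metadata, "morphotype"),
      habitat = groupMeans(summaries, metadata, "habitat")),
    partition = partition,
    habitat_table = habitatTable(summaries, metadata),
    tallies = tallies,
    consensus = consensus,
    architectures = archs,
    architectures_table = archTable,
    domain_frequency = domainFrequencyTable(unname(archs), calls),
    cooccurrence_nacht_wd40 = domainCooccurrence(unname(archs),
                                                 c("NACHT", "WD40")),
    tree = tree, tree_labels = treeLabels, clades = clades,
    run = list(seed = as.integer(seed),
               threshold = thr, calibrated_quantile_value = q,
               threshold_quantile = thresholdQuantile,
               threshold_floor = thresholdFloor,
               profile_self_score = selfScore(profile),
               n_proteins = nrow(proteins),
               version = as.character(utils::packageVersion("ocascan"))))
  checkReport(report, metadata)
  report
}

#' Verify the internal consistency of a study report
#'
#' Partition counts must sum to the strain count, tally totals must equal
#' the resolved call count, per-site tallies must be the marginals of the
#' per-dyad tallies, and strain summary counts must match the calls table.
#' Any violation is an error, not a warning.
#'
#' @param report a report from [runStudy()].
#' @param metadata the strain metadata the report was computed from.
#' @return TRUE invisibly.
#' @export
checkReport <- function(report, metadata) {
  p <- report$partition
  if (p$n_both + p$n_wt_only + p$n_mut_only + p$n_none != nrow(metadata))
    stop("report inconsistent: partition counts do not sum to strain count")
  t <- report$tallies
  if (sum(t$dyads) != t$n_resolved)
    stop("report inconsistent: dyad tally total != resolved call count")
  hMarg <- tapply(t$dyads, substr(names(t$dyads), 1, 1), sum)
  cMarg <- tapply(t$dyads, substr(names(t$dyads), 2, 2), sum)
  if (!isTRUE(all.equal(as.numeric(hMarg[names(t$h_site)]),
                        as.numeric(t$h_site))) ||
      !isTRUE(all.equal(as.numeric(cMarg[names(t$c_site)]),
                        as.numeric(t$c_site))))
    stop("report inconsistent: per-site tallies are not the dyad marginals")
  s <- report$strain_summaries
  resolved <- report$calls[report$calls$oca_class != "unresolved", ,
                           drop = FALSE]
  if (sum(s$n_wt) != sum(resolved$oca_class == "wild_type") ||
      sum(s$n_mut) != sum(resolved$oca_class == "mutated"))
    stop("report inconsistent: strain summary counts != call counts")
  invisible(TRUE)
}

#' Simulate a study and run the full pipeline on it
#'
#' @param config simulation configuration from [simulationConfig()].
#' @param seed integer seed used for both generation and analysis.
#' @param ... further arguments passed to [runStudy()].
#' @return list with `study` (the generated truth) and `report`.
#' @export
runSyntheticStudy <- function(config = defaultSimulationConfig(),
                              seed = config$seed, ...) {
  study <- generateStudy(config, seed = seed)
  report <- runStudy(study$proteins, study$metadata, study$annotations,
                     seed = seed, ...)
  list(study = study, report = report)
}
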