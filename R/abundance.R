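## Per-strain and per-group abundance statistics, strain partitions and
## habitat tables. Abundance is expressed as OCAs per 100 proteins of the
## strain's proteome.

#' Summarize orthocaspase content per strain
#'
#' Counts wild-type and mutated calls per strain and converts them to
#' abundances per 100 proteins using the metadata `proteome_size` as the
#' denominator. Every strain in the metadata gets a row (zeros when it has
#' no calls); a call referencing an unknown strain is an error. Abundances
#' are reported to 4 significant figures.
#'
#' @param calls calls table from [callActiveSites()]; unresolved calls are
#'   ignored.
#' @param metadata strain metadata table.
#' @return data.frame `strain_id`, `n_wt`, `n_mut`, `proteome_size`,
#'   `abundance_wt`, `abundance_mut`.
#' @export
summarizeStrains <- function(calls, metadata) {
  unknown <- setdiff(calls$strain_id, metadata$strain_id)
  if (length(unknown))
    stop("calls reference strains missing from metadata: ",
         paste(unknown, collapse = ", "))
  resolved <- calls[calls$oca_class %in% c("wild_type", "mutated"), ,
                    drop = FALSE]
  nwt <- table(factor(resolved$strain_id[resolved$oca_class == "wild_type"],
                      levels = metadata$strain_id))
  nmut <- table(factor(resolved$strain_id[resolved$oca_class == "mutated"],
                       levels = metadata$strain_id))
  out <- data.frame(
    strain_id = metadata$strain_id,
    n_wt = as.integer(nwt), n_mut = as.integer(nmut),
    proteome_size = metadata$proteome_size,
    stringsAsFactors = FALSE)
  out$abundance_wt <- signif(100 * out$n_wt / out$proteome_size, 4)
  out$abundance_mut <- signif(100 * out$n_mut / out$proteome_size, 4)
  out
}

#' Mean abundance by morphotype or habitat
#'
#' Unweighted arithmetic means of the per-strain abundances within each
#' group; groups without member strains are omitted.
#'
#' @param summaries per-strain summary from [summarizeStrains()].
#' @param metadata strain metadata table.
#' @param by grouping variable, `"morphotype"` or `"habitat"`.
#' @return data.frame `group`, `n_strains`, `mean_abundance_wt`,
#'   `mean_abundance_mut`.
#' @export
groupMeans <- function(summaries, metadata, by = c("morphotype", "habitat")) {
  by <- match.arg(by)
  g <- metadata[[by]][match(summaries$strain_id, metadata$strain_id)]
  if (anyNA(g)) stop("summary strain missing from metadata")
  levels <- if (by == "morphotype") MORPHOTYPES else HABITATS
  g <- factor(g, levels = levels)
  out <- do.call(rbind, lapply(levels(g)[table(g) > 0], function(lv) {
    s <- summaries[g == lv, , drop = FALSE]
    data.frame(group = lv, n_strains = nrow(s),
               mean_abundance_wt = mean(s$abundance_wt),
               mean_abundance_mut = mean(s$abundance_mut),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Partition strains by orthocaspase subtype content
#'
#' Classifies every analysed strain by whether it carries at least one
#' wild-type and/or at least one mutated orthocaspase.
#'
#' @param summaries per-strain summary from [summarizeStrains()].
#' @return list of counts `n_both`, `n_wt_only`, `n_mut_only`, `n_none`;
#'   they always sum to the number of strains.
#' @export
partitionStrains <- function(summaries) {
  wt <- summaries$n_wt > 0
  mut <- summaries$n_mut > 0
  list(n_both = sum(wt & mut), n_wt_only = sum(wt & !mut),
       n_mut_only = sum(!wt & mut), n_none = sum(!wt & !mut))
}

#' Habitat distribution of carrier strains
#'
#' For each orthocaspase subtype, the percentage of carrier strains found
#' in each habitat (denominator = carrier strains of that subtype), rounded
#' to the nearest integer.
#'
#' @param summaries per-strain summary from [summarizeStrains()].
#' @param metadata strain metadata table.
#' @return data.frame `habitat`, `pct_wt`, `pct_mut` (all habitats listed;
#'   `NA` percentages when a subtype has no carriers).
#' @export
habitatTable <- function(summaries, metadata) {
  h <- metadata$habitat[match(summaries$strain_id, metadata$strain_id)]
  if (anyNA(h)) stop("summary strain missing from metadata")
  h <- factor(h, levels = HABITATS)
  pct <- function(carrier) {
    if (!sum(carrier)) return(rep(NA_real_, length(HABITATS)))
    as.vector(round(100 * table(h[carrier]) / sum(carrier)))
  }
  data.frame(habitat = HABITATS,
             pct_wt = pct(summaries$n_wt > 0),
             pct_mut = pct(summaries$n_mut > 0),
             stringsAsFactors = FALSE)
}
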