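## Hydropathy-based transmembrane prediction, whole-protein domain
## architectures, topology calls, and domain occurrence statistics.

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' Computes Kyte-Doolittle window means centred on every eligible residue
#' (ambiguity letters score 0), finds maximal runs of window centres whose
#' mean reaches the threshold, expands each run to the full window extent
#' and merges overlapping runs.
#'
#' @param sequence amino-acid string.
#' @param window odd window length; default 19.
#' @param threshold minimum window-mean hydropathy; default 1.6.
#' @return data.frame with `start`, `end` (1-based inclusive) and
#'   `mean_hydropathy` (mean of the contributing window means); zero rows
#'   when no segment is found or the sequence is shorter than the window.
#' @examples
#' predictTM(paste0(strrep("S", 30), strrep("L", 21), strrep("S", 30)))
#' @export
predictTM <- function(sequence, window = 19L, threshold = 1.6) {
  stopifnot(window %% 2 == 1, window >= 3)
  empty <- data.frame(start = integer(), end = integer(),
                      mean_hydropathy = numeric())
  L <- nchar(sequence)
  if (L < window) return(empty)
  v <- KD_SCALE[strsplit(sequence, "")[[1]]]
  v[is.na(v)] <- 0  # X/B/Z
  cs <- cumsum(c(0, v))
  half <- (window - 1L) / 2L
  centres <- (half + 1L):(L - half)
  wm <- (cs[centres + half + 1L] - cs[centres - half]) / window
  hot <- wm >= threshold
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(a = centres[starts[r$values]],
                     b = centres[ends[r$values]])
  runs$start <- runs$a - half
  runs$end <- runs$b + half
  ## window means of the centres inside each maximal run
  means <- Map(function(a, b) wm[(a - half):(b - half)], runs$a, runs$b)
  ## merge overlapping expanded runs, pooling their centre window means
  out <- data.frame(start = integer(), end = integer(),
                    mean_hydropathy = numeric())
  accStart <- runs$start[1]; accEnd <- runs$end[1]; accMeans <- means[[1]]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs$start[i] <= accEnd + 1L) {
      accEnd <- max(accEnd, runs$end[i])
      accMeans <- c(accMeans, means[[i]])
    } else {
      out <- rbind(out, data.frame(start = accStart, end = accEnd,
                                   mean_hydropathy = mean(accMeans))[
                                     , c("start", "end", "mean_hydropathy")])
      accStart <- runs$start[i]; accEnd <- runs$end[i]; accMeans <- means[[i]]
    }
  }
  out <- rbind(out, data.frame(start = accStart, end = accEnd,
                               mean_hydropathy = mean(accMeans)))
  rownames(out) <- NULL
  out
}

#' Collapse successive domain repeats
#'
#' Consecutive identical names are collapsed, then de-duplicated to the set
#' used for per-protein occurrence counting, so a protein contributes one
#' count per domain type however many copies it carries.
#'
#' @param elements ordered character vector of domain names.
#' @return character vector of unique names (first-occurrence order).
#' @examples
#' collapseRepeats(c("WD40", "WD40", "WD40", "NACHT"))
#' @export
collapseRepeats <- function(elements) {
  if (!length(elements)) return(character())
  unique(rle(as.character(elements))$values)
}

#' Assemble a whole-protein domain architecture
#'
#' Merges the protein's p20 hit(s), accessory-domain annotations and
#' predicted transmembrane segments into one ordered element list. An
#' accessory annotation overlapping a p20 hit by more than half of its own
#' length is dropped (it is the catalytic domain re-called under a database
#' alias); overlapping accessory annotations sharing a name are merged with
#' a warning.
#'
#' @param proteinId protein identifier.
#' @param p20Hits data.frame of the protein's hits (`start`, `end`).
#' @param annotations data.frame of accessory domains (`domain_name`,
#'   `start`, `end`); may be empty or NULL.
#' @param tms data.frame from [predictTM()].
#' @param sequenceLength protein length, for coordinate validation.
#' @return a [DomainArchitecture-class].
#' @export
buildArchitecture <- function(proteinId, p20Hits, annotations = NULL,
                              tms = NULL, sequenceLength) {
  el <- data.frame(name = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  if (!is.null(p20Hits) && nrow(p20Hits))
    el <- rbind(el, data.frame(name = "p20", start = p20Hits$start,
                               end = p20Hits$end))
  if (!is.null(annotations) && nrow(annotations)) {
    ann <- data.frame(name = annotations$domain_name,
                      start = annotations$start, end = annotations$end,
                      stringsAsFactors = FALSE)
    if (!is.null(p20Hits) && nrow(p20Hits)) {
      ovl <- vapply(seq_len(nrow(ann)), function(i) {
        max(vapply(seq_len(nrow(p20Hits)), function(k)
          max(0L, min(ann$end[i], p20Hits$end[k]) -
                max(ann$start[i], p20Hits$start[k]) + 1L), 0L))
      }, 0L)
      frac <- ovl / (ann$end - ann$start + 1L)
      ann <- ann[frac <= 0.5, , drop = FALSE]
    }
    ## merge overlapping same-name annotations
    if (nrow(ann) > 1) {
      ann <- ann[order(ann$name, ann$start), , drop = FALSE]
      keep <- list()
      for (i in seq_len(nrow(ann))) {
        last <- if (length(keep)) keep[[length(keep)]] else NULL
        if (!is.null(last) && last$name == ann$name[i] &&
            ann$start[i] <= last$end) {
          warning("merging overlapping ", last$name, " annotations in ",
                  proteinId)
          keep[[length(keep)]]$end <- max(last$end, ann$end[i])
        } else keep[[length(keep) + 1L]] <- ann[i, ]
      }
      ann <- do.call(rbind, keep)
    }
    el <- rbind(el, ann)
  }
  if (!is.null(tms) && nrow(tms))
    el <- rbind(el, data.frame(name = "TM", start = tms$start,
                               end = tms$end))
  if (nrow(el) && (any(el$start < 1) || any(el$end > sequenceLength)))
    stop("element coordinates outside sequence for ", proteinId)
  el <- el[order(el$start, el$end, el$name), , drop = FALSE]
  rownames(el) <- NULL
  nP20 <- sum(el$name == "p20")
  methods::new("DomainArchitecture", proteinId = proteinId, elements = el,
               architectureString = paste(el$name, collapse = "—"),
               uniqueDomains = setdiff(collapseRepeats(el$name),
                                       c("p20", "TM")),
               multiP20 = nP20 > 1)
}

#' Classify membrane topology
#'
#' A protein lacking a transmembrane segment is cytoplasmic; one containing
#' a transmembrane segment is membrane-bound, and the first p20 hit is
#' reported as N- or C-terminal of its nearest transmembrane segment.
#'
#' @param arch a [DomainArchitecture-class].
#' @return list with `protein_id`, `localization`
#'   (`cytoplasmic`/`membrane_bound`), `p20_side`
#'   (`p20_N_of_TM`/`p20_C_of_TM`/`none`), and `n_tm`.
#' @export
classifyTopology <- function(arch) {
  el <- arch@elements
  tm <- el[el$name == "TM", , drop = FALSE]
  p20 <- el[el$name == "p20", , drop = FALSE]
  if (!nrow(tm))
    return(list(protein_id = arch@proteinId, localization = "cytoplasmic",
                p20_side = "none", n_tm = 0L))
  side <- "none"
  if (nrow(p20)) {
    p <- p20[1, ]
    gap <- pmax(tm$start - p$end, p$start - tm$end, 0L)
    nearest <- tm[which.min(gap), ]
    side <- if (nearest$start < p$start) "p20_C_of_TM" else "p20_N_of_TM"
  }
  list(protein_id = arch@proteinId, localization = "membrane_bound",
       p20_side = side, n_tm = nrow(tm))
}

#' Accessory-domain occurrence table
#'
#' Counts, per accessory domain, the proteins containing it (once each,
#' after repeat collapsing), the percentage of all analysed p20-containing
#' proteins, and the split across wild-type and mutated dyad classes.
#'
#' @param archs list of [DomainArchitecture-class] objects.
#' @param calls calls table (for the per-class split); matched by
#'   `protein_id`.
#' @return data.frame `domain`, `n`, `pct`, `n_wild_type`, `n_mutated`,
#'   sorted by descending `n` then name; zero rows for an empty study.
#' @export
domainFrequencyTable <- function(archs, calls = NULL) {
  if (!length(archs))
    return(data.frame(domain = character(), n = integer(), pct = numeric(),
                      n_wild_type = integer(), n_mutated = integer()))
  ids <- vapply(archs, function(a) a@proteinId, "")
  doms <- lapply(archs, uniqueDomains)
  cls <- if (is.null(calls)) rep(NA_character_, length(ids)) else
    calls$oca_class[match(ids, calls$protein_id)]
  all_doms <- sort(unique(unlist(doms)))
  n <- vapply(all_doms, function(d)
    sum(vapply(doms, function(s) d %in% s, TRUE)), 0L)
  nwt <- vapply(all_doms, function(d)
    sum(vapply(seq_along(doms), function(i)
      d %in% doms[[i]] && identical(cls[i], "wild_type"), TRUE)), 0L)
  nmut <- vapply(all_doms, function(d)
    sum(vapply(seq_along(doms), function(i)
      d %in% doms[[i]] && identical(cls[i], "mutated"), TRUE)), 0L)
  out <- data.frame(domain = all_doms, n = n,
                    pct = round(100 * n / length(archs), 2),
                    n_wild_type = nwt, n_mutated = nmut,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count proteins carrying both domains of a pair
#'
#' @param archs list of [DomainArchitecture-class] objects.
#' @param pair character vector of two domain names.
#' @return integer count of proteins whose collapsed domain sets contain
#'   both names.
#' @export
domainCooccurrence <- function(archs, pair) {
  stopifnot(length(pair) == 2, all(nzchar(pair)))
  sum(vapply(archs, function(a) all(pair %in% uniqueDomains(a)), TRUE))
}
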