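## Readers and writers for every external format the pipeline touches.

#' Read a per-strain proteome FASTA
#'
#' Reads an amino-acid FASTA file into a protein table. Protein identifiers
#' are the first whitespace-delimited token of each header; sequences are
#' upper-cased and a single terminal `*` stop is stripped. The 20 standard
#' residues plus the ambiguity letters X/B/Z are accepted.
#'
#' @param path path to a FASTA file.
#' @param strainId strain identifier attached to every record.
#' @return data.frame with columns `strain_id`, `protein_id`, `sequence`,
#'   in file order.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 desc", "MFSGHG"), f)
#' readProteomeFasta(f, "S")
#' @export
readProteomeFasta <- function(path, strainId) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("no such file: ", path)
  ## read as raw byte strings: the AA reader silently drops invalid
  ## letters, and we must report them with their position instead
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (",
                             conditionMessage(e), ")"))
  if (length(aa) == 0) stop("FASTA file has no records: ", path)
  ids <- vapply(strsplit(names(aa), "[ \t]+"), `[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate protein_id within strain ", strainId, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence for ", ids[!nzchar(seqs)][1])
  bad <- regexpr(sprintf("[^%s]", paste(c(AMINO_ACIDS, AMBIGUOUS_AA),
                                        collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid residue '%s' at position %d of %s",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  data.frame(strain_id = strainId, protein_id = unname(ids),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a protein table as FASTA
#'
#' @param proteins data.frame with `protein_id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteomeFasta <- function(proteins, path) {
  con <- file(path, open = "wb")  # byte-stable across platforms
  on.exit(close(con))
  writeLines(rbind(paste0(">", proteins$protein_id), proteins$sequence),
             con, sep = "\n")
  invisible(path)
}

#' Read the strain metadata table
#'
#' Tab-separated with header columns `strain_id`, `morphotype`, `habitat`,
#' `proteome_size`. Morphotype must be one of unicellular, filamentous,
#' heterocytous; habitat one of freshwater, marine, terrestrial, symbiotic,
#' other. `proteome_size` is the total number of proteins in the strain's
#' proteome, used as the abundance denominator.
#'
#' @param path path to the TSV file.
#' @return data.frame with validated columns; `proteome_size` integer.
#' @export
readStrainMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("strain_id", "morphotype", "habitat", "proteome_size")
  if (!all(need %in% names(md)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  md <- md[need]
  if (anyDuplicated(md$strain_id))
    stop("duplicate strain_id: ",
         paste(unique(md$strain_id[duplicated(md$strain_id)]), collapse = ", "))
  badm <- setdiff(unique(md$morphotype), MORPHOTYPES)
  if (length(badm))
    stop("unknown morphotype '", badm[1], "'; allowed: ",
         paste(MORPHOTYPES, collapse = ", "))
  badh <- setdiff(unique(md$habitat), HABITATS)
  if (length(badh))
    stop("unknown habitat '", badh[1], "'; allowed: ",
         paste(HABITATS, collapse = ", "))
  n <- suppressWarnings(as.numeric(md$proteome_size))
  if (any(is.na(n)) || any(n <= 0) || any(n != round(n)))
    stop("proteome_size must be a positive integer")
  md$proteome_size <- as.integer(n)
  md
}

#' Read an accessory-domain annotation table
#'
#' Accepts either a simple 4/5-column TSV (`protein_id`, `domain_name`,
#' `start`, `end`, optional `score`) or an hmmscan `--domtblout` file
#' (comment lines starting with `#`, whitespace-separated, alignment
#' coordinates taken from the ali-coord columns). The dialect is
#' auto-detected. Coordinates are 1-based inclusive; rows are returned
#' sorted by (`protein_id`, `start`).
#'
#' @param path path to the annotation file.
#' @return data.frame with columns `protein_id`, `domain_name`, `start`,
#'   `end`, `score` (`NA` when absent).
#' @export
readDomainTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(protein_id = character(), domain_name = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  body <- lines[!startsWith(lines, "#")]
  nf <- length(strsplit(trimws(body[1]), "[ \t]+")[[1]])
  if (any(startsWith(lines, "#")) || nf >= 20) {
    ## hmmscan domtblout: target(domain) name is field 1, query(protein)
    ## field 4, domain score field 14, ali coords fields 18-19
    fields <- strsplit(trimws(body), "[ \t]+")
    if (any(lengths(fields) < 19))
      stop("unknown annotation dialect: too few columns for domtblout")
    ann <- data.frame(
      protein_id  = vapply(fields, `[`, "", 4),
      domain_name = vapply(fields, `[`, "", 1),
      start = as.integer(vapply(fields, `[`, "", 18)),
      end   = as.integer(vapply(fields, `[`, "", 19)),
      score = as.numeric(vapply(fields, `[`, "", 14)),
      stringsAsFactors = FALSE)
  } else if (nf %in% c(4L, 5L)) {
    fields <- strsplit(body, "\t")
    if (!all(lengths(fields) %in% c(4L, 5L)))
      stop("unknown annotation dialect: ragged simple TSV")
    ann <- data.frame(
      protein_id  = vapply(fields, `[`, "", 1),
      domain_name = vapply(fields, `[`, "", 2),
      start = as.integer(vapply(fields, `[`, "", 3)),
      end   = as.integer(vapply(fields, `[`, "", 4)),
      score = as.numeric(vapply(fields, function(f)
        if (length(f) >= 5) f[5] else NA_character_, "")),
      stringsAsFactors = FALSE)
  } else stop("unknown annotation dialect (", nf, " columns)")
  if (any(is.na(ann$start)) || any(is.na(ann$end)))
    stop("non-numeric domain coordinates")
  if (any(ann$start > ann$end))
    stop("start > end for ", ann$protein_id[ann$start > ann$end][1])
  if (any(ann$start < 1)) stop("coordinates must be 1-based positive")
  if (any(!nzchar(ann$domain_name))) stop("empty domain_name")
  ann[order(ann$protein_id, ann$start), , drop = FALSE]
}

## Deterministic TSV writer: tab separator, '.' decimal, no quotes, LF.
writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write the full study result file set
#'
#' Writes the per-protein calls table, the per-strain summary table, a JSON
#' file with tallies, partitions, consensus patterns and run metadata, the
#' architecture and domain-frequency tables, and the dyad-labelled newick
#' tree. Output is byte-stable for fixed inputs; the newick file is omitted
#' when the study has no tree.
#'
#' @param report a study report from [runStudy()].
#' @param outDir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
writeStudyResults <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 6,
                                                   scientific = FALSE,
                                                   trim = TRUE))
  paths <- character()
  calls <- report$calls
  calls_out <- calls[setdiff(names(calls), "col_map")]
  if ("score" %in% names(calls_out)) calls_out$score <- fmt(calls_out$score)
  p <- file.path(outDir, "calls.tsv"); writeTsv(calls_out, p)
  paths <- c(paths, p)

  p <- file.path(outDir, "strain_summary.tsv")
  writeTsv(report$strain_summaries, p); paths <- c(paths, p)

  if (!is.null(report$architectures_table)) {
    p <- file.path(outDir, "architecture.tsv")
    writeTsv(report$architectures_table, p); paths <- c(paths, p)
  }
  if (!is.null(report$domain_frequency)) {
    p <- file.path(outDir, "domain_frequency.tsv")
    df <- report$domain_frequency
    df$pct <- fmt(df$pct)
    writeTsv(df, p); paths <- c(paths, p)
  }

  tall <- list(
    tallies = report$tallies,
    partition = report$partition,
    habitat_table = report$habitat_table,
    group_means = report$group_means,
    consensus = report$consensus,
    run = report$run)
  p <- file.path(outDir, "tallies.json")
  con <- file(p, open = "wb")
  writeLines(jsonlite::toJSON(tall, auto_unbox = TRUE, digits = 10,
                              null = "null", na = "null", pretty = TRUE),
             con, sep = "\n")
  close(con)
  paths <- c(paths, p)

  if (!is.null(report$tree)) {
    tr <- report$tree
    if (!is.null(report$tree_labels)) {
      lab <- report$tree_labels[tr$tip.label]
      tr$tip.label <- ifelse(is.na(lab), tr$tip.label,
                             paste0(tr$tip.label, "|", lab))
    }
    p <- file.path(outDir, "tree.newick")
    con <- file(p, open = "wb")
    writeLines(ape::write.tree(tr), con, sep = "\n")
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
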