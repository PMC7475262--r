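## Shared fixtures, built in code at test time.

HYDROPHILIC_SET <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G")

randomHydrophilic <- function(n) {
  paste(sample(HYDROPHILIC_SET, n, replace = TRUE), collapse = "")
}

randomProtein <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

## A tiny handcrafted seed: 4 rows, 12 columns, H at column 5, C at 9.
tinySeed <- function() {
  SeedAlignment(c("AGFSHGDTCHSK",
                  "AGFSHGDTCHSK",
                  "AGFSHGDACHSR",
                  "TGFSHGDTCHSK"), hCol = 5, cCol = 9)
}

## One-row protein table for scanning helpers.
proteinRow <- function(seq, pid = "p1", sid = "S") {
  data.frame(strain_id = sid, protein_id = pid, sequence = seq,
             stringsAsFactors = FALSE)
}

## Independent re-scoring of a hit from its column map: emission scores for
## mapped columns plus affine gap costs read off the col_map pattern
## (runs of NA between mapped columns = deletions; jumps in query index
## between consecutive mapped columns = insertions). Used as an oracle for
## the aligner's reported score and alignment path.
scoreFromColMap <- function(profile, sequence, hit) {
  cm <- hit$col_map[[1]]
  codes <- match(strsplit(sequence, "")[[1]],
                 c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V"))
  codes[is.na(codes)] <- 21L
  mapped <- which(!is.na(cm))
  S <- profile@scores
  total <- sum(vapply(mapped, function(j) S[codes[cm[j]], j], 0.0))
  gapCost <- function(len) profile@gapOpen + (len - 1) * profile@gapExtend
  for (k in seq_along(mapped)[-1]) {
    jPrev <- mapped[k - 1]; j <- mapped[k]
    del <- j - jPrev - 1L                     # skipped profile columns
    ins <- cm[j] - cm[jPrev] - 1L             # skipped query residues
    if (del > 0) total <- total + gapCost(del)
    if (ins > 0) total <- total + gapCost(ins)
  }
  total
}

## Brute-force TM oracle: O(L * window) recomputation of every window mean,
## then the same run-expansion and merge definition applied naively.
bruteTM <- function(sequence, window = 19L, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
          Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
          L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
          S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  L <- nchar(sequence)
  if (L < window) return(data.frame(start = integer(), end = integer()))
  ch <- strsplit(sequence, "")[[1]]
  half <- (window - 1L) / 2L
  hotCentres <- integer()
  for (c in (half + 1L):(L - half)) {
    vals <- kd[ch[(c - half):(c + half)]]
    vals[is.na(vals)] <- 0
    if (mean(vals) >= threshold) hotCentres <- c(hotCentres, c)
  }
  if (!length(hotCentres)) return(data.frame(start = integer(),
                                             end = integer()))
  ## intervals centre +- half, merged when overlapping or adjacent
  iv <- cbind(hotCentres - half, hotCentres + half)
  out <- list(); cur <- iv[1, ]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] <= cur[2] + 1L) cur[2] <- max(cur[2], iv[r, 2])
    else { out[[length(out) + 1L]] <- cur; cur <- iv[r, ] }
  }
  out[[length(out) + 1L]] <- cur
  data.frame(start = vapply(out, `[`, 0, 1), end = vapply(out, `[`, 0, 2))
}

## Unrooted split set of a phylo tree, as sorted "A|B" strings over sorted
## tip subsets; topology comparison helper.
splitSet <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  nt <- length(tips)
  inner <- setdiff(unique(tree$edge[, 1]), seq_len(nt))
  splits <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= nt) next
    below <- sort(ape::extract.clade(tree, child)$tip.label)
    if (length(below) <= 1 || length(below) >= nt - 1) next
    side <- if (tips[1] %in% below) below else setdiff(tips, below)
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  sort(unique(splits))
}
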