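test_that("hits project onto profile columns with gaps for deletions", {
  prof <- buildProfile(exampleSeedAlignment())
  cons <- consensusSequence(prof)
  p <- rbind(proteinRow(paste0(strrep("S", 10), cons), pid = "a"),
             proteinRow(paste0(strrep("T", 5), cons), pid = "b"))
  hits <- scanProteins(prof, p)
  aln <- projectAlignment(hits, p)
  expect_equal(nrow(aln), 2L)
  expect_equal(ncol(aln), profileLength(prof))
  expect_equal(paste(aln["a", ], collapse = ""), cons)
  expect_identical(aln["a", ], aln["b", ])

  ## deleting column 7's residue leaves '-' at column 7
  ch <- strsplit(cons, "")[[1]][-7]
  p3 <- proteinRow(paste(ch, collapse = ""), pid = "c")
  h3 <- scanProtein(prof, p3, threshold = -Inf)[1, ]
  h3$strain_id <- "S"
  aln3 <- projectAlignment(h3, p3)
  expect_equal(unname(aln3[1, 7]), "-")

  dup <- hits; dup$protein_id <- c("a", "a")
  expect_error(projectAlignment(dup, p), "duplicate")
})

test_that("p-distance counts mismatches over gap-free columns", {
  A <- rbind(a = strsplit(strrep("A", 100), "")[[1]],
             b = strsplit(paste0(strrep("A", 95), strrep("C", 5)), "")[[1]])
  expect_equal(pDistance(A, "a", "a"), 0)
  expect_equal(pDistance(A, "a", "b"), 0.05)
  A2 <- A; A2["b", 1:90] <- "-"
  expect_warning(d <- pDistance(A2, "a", "b"), "fewer than 20")
  expect_equal(d, 1)
  ## symmetry + identity over random matrices
  set.seed(13)
  for (k in 1:5) {
    M <- matrix(sample(c("A", "C", "G", "-"), 3 * 60, replace = TRUE), 3,
                dimnames = list(c("x", "y", "z"), NULL))
    dm <- suppressWarnings(pDistanceMatrix(M))
    expect_equal(dm, t(dm))
    expect_equal(diag(dm), c(x = 0, y = 0, z = 0))
    expect_true(all(dm >= 0 & dm <= 1))
  }
})

test_that("three taxa reproduce the closed-form branch lengths", {
  dm <- matrix(c(0, 0.3, 0.4,
                 0.3, 0, 0.5,
                 0.4, 0.5, 0), 3, dimnames = list(c("A", "B", "C"),
                                                  c("A", "B", "C")))
  tr <- njTree(dm)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(unname(lens["A"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(lens["B"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(lens["C"]), (0.4 + 0.5 - 0.3) / 2)
  expect_error(njTree(dm[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers the split of a 4-taxon additive matrix", {
  ## tree ((A:1,B:2):1,(C:3,D:1))
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 3
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 4
  dm["C", "D"] <- dm["D", "C"] <- 4
  tr <- njTree(dm)
  expect_equal(splitSet(tr), "A,B")
  ## four-point condition agrees: AB|CD pairing is minimal
  expect_lt(dm["A", "B"] + dm["C", "D"],
            min(dm["A", "C"] + dm["B", "D"], dm["A", "D"] + dm["B", "C"]))
})

test_that("NJ topology is invariant to taxon order and matches ape", {
  set.seed(19)
  for (k in 1:10) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n, br = function(x) stats::runif(x, 0.1, 1))
    dm <- ape::cophenetic.phylo(true)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    tr <- njTree(dm)
    expect_equal(splitSet(tr), splitSet(true))
    perm <- sample(rownames(dm))
    expect_equal(splitSet(njTree(dm[perm, perm])), splitSet(true))
    ## independent route: ape's NJ implementation
    expect_equal(splitSet(ape::nj(dm)), splitSet(tr))
  }
})

test_that("outgroup rooting bisects the pendant edge and is idempotent", {
  dm <- matrix(c(0, 0.2, 0.6,
                 0.2, 0, 0.6,
                 0.6, 0.6, 0), 3, dimnames = list(c("A", "B", "O"),
                                                  c("A", "B", "O")))
  tr <- njTree(dm)
  rt <- rootWithOutgroup(tr, "O")
  expect_true(ape::is.rooted(rt))
  root <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  expect_true(match("O", rt$tip.label) %in% kids)
  rootLens <- rt$edge.length[rt$edge[, 1] == root]
  expect_equal(rootLens[1], rootLens[2])  # midpoint of the pendant edge
  rt2 <- rootWithOutgroup(rt, "O")
  expect_equal(splitSet(rt2), splitSet(rt))
  expect_equal(sum(rt$edge.length), sum(tr$edge.length))
  expect_error(rootWithOutgroup(tr, "Z"), "outgroup")
})

test_that("pure clades are maximal label-pure subtrees", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  labels <- c(a = "YS", b = "YS", c = "YS", d = "HC")
  rep <- pureClades(tr, labels, minSize = 2)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$label, "YS")
  expect_setequal(rep$leaves[[1]], c("a", "b", "c"))

  labels2 <- c(a = "1", b = "2", c = "3", d = "4")
  expect_equal(nrow(pureClades(tr, labels2, minSize = 2)), 0L)
  expect_error(pureClades(tr, labels[-1]), "unlabelled")
})

test_that("pure clades equal a brute-force scan of every internal node", {
  set.seed(23)
  labs <- c("HC", "YS", "YN")
  for (k in 1:10) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)
    labels <- setNames(sample(labs, n, replace = TRUE), tr$tip.label)
    got <- pureClades(tr, labels, minSize = 2)
    ## brute force: every internal node whose tips share a label and whose
    ## parent's tips do not
    nt <- length(tr$tip.label)
    tipsUnder <- function(node)
      if (node <= nt) tr$tip.label[node] else
        ape::extract.clade(tr, node)$tip.label
    pure <- function(node) {
      u <- unique(unname(labels[tipsUnder(node)]))
      if (length(u) == 1) u else NA_character_
    }
    want <- list()
    for (node in (nt + 1):(nt + tr$Nnode)) {
      lab <- pure(node)
      if (is.na(lab)) next
      par <- tr$edge[tr$edge[, 2] == node, 1]
      if (length(par) && !is.na(pure(par))) next
      tips <- tipsUnder(node)
      if (length(tips) >= 2) want[[length(want) + 1L]] <-
          list(label = lab, tips = sort(tips))
    }
    expect_equal(nrow(got), length(want))
    gotSets <- lapply(seq_len(nrow(got)), function(i)
      sort(got$leaves[[i]]))
    wantSets <- lapply(want, `[[`, "tips")
    expect_setequal(vapply(gotSets, paste, "", collapse = ","),
                    vapply(wantSets, paste, "", collapse = ","))
  }
})

test_that("divergent dyad groups come out as near-complete pure clades", {
  sim <- simulateDyadGroups(c(YS = 12, YN = 8), seed = 3)
  prof <- buildProfile(exampleSeedAlignment())
  hits <- scanProteins(prof, sim$proteins, threshold = 0.2 *
                         selfScore(prof))
  expect_setequal(hits$protein_id, sim$proteins$protein_id)
  aln <- projectAlignment(hits, sim$proteins)
  tr <- njTree(pDistanceMatrix(aln))
  rt <- rootWithOutgroup(tr, sim$outgroup_id)
  rep <- pureClades(rt, sim$labels, minSize = 2, exclude = "outgroup")
  for (lab in c("YS", "YN")) {
    sz <- rep$size[rep$label == lab]
    expect_gte(max(sz, 0) / sum(sim$labels == lab), 0.9)
  }
})
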