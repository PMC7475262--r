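test_that("profile scores follow the log-odds formula", {
  ## column 2: H x9, Y x1; column 3: C x10
  rows <- c(rep("AHCG", 9), "AYCG")
  seed <- SeedAlignment(rows, hCol = 2, cCol = 3)
  prof <- buildProfile(seed, pseudocount = 1)
  bg <- 1 / 20
  expected <- function(count, total) log2(((count + 1 * bg) / (total + 1)) / bg)
  expect_equal(unname(prof@scores["H", 2]), expected(9, 10))
  expect_equal(unname(prof@scores["Y", 2]), expected(1, 10))
  expect_equal(unname(prof@scores["W", 2]), expected(0, 10))
  expect_true(prof@scores["H", 2] > prof@scores["Y", 2])
  expect_true(prof@scores["Y", 2] > prof@scores["W", 2])
})

test_that("majority-gap columns are dropped and dyad columns re-indexed", {
  rows <- c("A-HCG", "A-HCG", "A-HCG", "T-HCG")
  seed <- SeedAlignment(rows, hCol = 3, cCol = 4)
  prof <- buildProfile(seed)
  expect_equal(profileLength(prof), 4L)
  expect_equal(unname(dyadColumns(prof)), c(2L, 3L))

  bad <- SeedAlignment(c("AH-CG", "AH-CG", "AHCCG", "AH-CG"),
                       hCol = 2, cCol = 3)
  expect_error(buildProfile(bad), "catalytic column")
})

test_that("a degenerate two-row seed reproduces its row as consensus", {
  rows <- rep("MGFSHGDTCHSK", 2)
  seed <- SeedAlignment(rows, hCol = 5, cCol = 9)
  prof <- buildProfile(seed)
  expect_equal(profileLength(prof), 12L)
  expect_equal(consensusSequence(prof), rows[1])
})

test_that("no query outscores the profile consensus", {
  prof <- buildProfile(tinySeed())
  set.seed(42)
  for (k in 1:25) {
    q <- randomProtein(sample(50:200, 1))
    h <- scanProtein(prof, proteinRow(q), threshold = -Inf)
    if (nrow(h)) expect_lte(max(h$score), selfScore(prof) + 1e-9)
  }
})

test_that("hits are shift-equivariant", {
  prof <- buildProfile(exampleSeedAlignment())
  cons <- consensusSequence(prof)
  set.seed(7)
  left <- randomHydrophilic(40)
  tailSeq <- randomHydrophilic(60)
  h1 <- scanProtein(prof, proteinRow(paste0(left, cons, tailSeq)))
  h2 <- scanProtein(prof, proteinRow(paste0(randomHydrophilic(10), left,
                                            cons, tailSeq)))
  expect_equal(h2$start - h1$start, 10L)
  expect_equal(h2$end - h1$end, 10L)
  expect_equal(h1$score, h2$score)
})

test_that("two planted copies give two non-overlapping hits", {
  prof <- buildProfile(exampleSeedAlignment())
  cons <- consensusSequence(prof)
  set.seed(3)
  q <- paste0(randomHydrophilic(30), cons, randomHydrophilic(50), cons,
              randomHydrophilic(30))
  h <- scanProtein(prof, proteinRow(q))
  expect_equal(nrow(h), 2L)
  expect_true(h$start[2] > h$end[1])
  expect_equal(h$score, rep(selfScore(prof), 2))
})

test_that("reported scores agree with an independent re-scoring of the path", {
  prof <- buildProfile(exampleSeedAlignment())
  cons <- consensusSequence(prof)
  set.seed(11)
  for (k in 1:5) {
    ## delete a random block and substitute residues to force gapped paths
    ch <- strsplit(cons, "")[[1]]
    del <- sample(20:130, 1)
    ch <- ch[-(del:(del + sample(1:3, 1)))]
    sub <- sample(seq_along(ch), 10)
    ch[sub] <- sample(c("A","G","S","T","N"), 10, replace = TRUE)
    q <- paste0(randomHydrophilic(25), paste(ch, collapse = ""),
                randomHydrophilic(25))
    h <- scanProtein(prof, proteinRow(q), threshold = -Inf)[1, ]
    expect_equal(h$score, scoreFromColMap(prof, q, h), tolerance = 1e-9)
    cm <- h$col_map[[1]]
    mapped <- cm[!is.na(cm)]
    expect_true(all(diff(mapped) > 0))                 # strictly increasing
    expect_true(all(mapped >= h$start & mapped <= h$end))
  }
})

test_that("catalytic positions map by offset arithmetic and honour deletions", {
  prof <- buildProfile(exampleSeedAlignment())
  cons <- consensusSequence(prof)
  q <- paste0(strrep("S", 9), cons)    # ungapped hit starting at residue 10
  h <- scanProtein(prof, proteinRow(q))
  pos <- mapCatalyticPositions(prof, h$col_map[[1]])
  expect_equal(unname(pos), c(9L + 58L, 9L + 112L))

  ## delete the catalytic C column from the query
  ch <- strsplit(cons, "")[[1]][-112]
  h2 <- scanProtein(prof, proteinRow(paste(ch, collapse = "")),
                    threshold = -Inf)[1, ]
  pos2 <- mapCatalyticPositions(prof, h2$col_map[[1]])
  expect_true(is.na(pos2[["c"]]))
  expect_false(is.na(pos2[["h"]]))
})

test_that("threshold calibration honours the quantile contract", {
  prof <- buildProfile(tinySeed())
  set.seed(5)
  bg <- data.frame(protein_id = sprintf("b%03d", 1:300),
                   sequence = replicate(300, randomProtein(120)),
                   stringsAsFactors = FALSE)
  expect_error(calibrateThreshold(prof, bg, quantile = 1.2), "quantile")
  expect_error(calibrateThreshold(prof, bg[1:50, ]), "at least 100")
  t99 <- calibrateThreshold(prof, bg, quantile = 0.99)
  t999 <- calibrateThreshold(prof, bg, quantile = 0.999)
  expect_gte(t999, t99)
  expect_identical(t999, calibrateThreshold(prof, bg, quantile = 0.999))
  ## direct sort-and-count: fraction of best scores >= threshold ~ 1 - q
  best <- vapply(bg$sequence, function(s)
    scanProtein(prof, proteinRow(s), threshold = -Inf)$score[1], 0.0,
    USE.NAMES = FALSE)
  expect_lte(mean(best > t99), 0.011 + 1 / nrow(bg))
})

test_that("planted domains are detected and background stays silent", {
  prof <- buildProfile(exampleSeedAlignment())
  set.seed(9)
  planted <- do.call(rbind, lapply(1:20, function(i) {
    lab <- sample(c("HC", "YS", "YN"), 1)
    proteinRow(plantOca(lab)$sequence, pid = sprintf("oca%02d", i))
  }))
  bgSeqs <- data.frame(
    strain_id = "S", protein_id = sprintf("bg%04d", 1:1000),
    sequence = replicate(1000, generateBackgroundProtein(
      sample(100:300, 1))),
    stringsAsFactors = FALSE)
  thr <- max(calibrateThreshold(prof, bgSeqs, 0.999),
             0.25 * selfScore(prof))
  scoreThreshold(prof) <- thr
  hp <- scanProteins(prof, planted)
  expect_equal(sort(unique(hp$protein_id)), sort(planted$protein_id))
  hb <- scanProteins(prof, bgSeqs)
  expect_lte(nrow(hb), 2)  # <= 0.2% false positives
})
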