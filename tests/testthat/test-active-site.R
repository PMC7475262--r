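test_that("dyad classification is total and singles out HC", {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  wt <- 0L
  for (h in aa) for (c in aa) {
    cl <- classifyDyad(h, c)
    expect_equal(cl$dyad_label, paste0(h, c))
    if (cl$oca_class == "wild_type") wt <- wt + 1L
    expect_true(cl$oca_class %in% c("wild_type", "mutated"))
    expect_equal(cl$oca_class == "wild_type", h == "H" && c == "C")
  }
  expect_equal(wt, 1L)
})

test_that("unresolved positions and bad input are handled", {
  expect_equal(classifyDyad(NA, "C")$oca_class, "unresolved")
  expect_equal(classifyDyad(NA, "C")$dyad_label, "-C")
  expect_equal(classifyDyad("H", NA)$dyad_label, "H-")
  expect_error(classifyDyad("1", "C"), "residue")
})

test_that("pocket windows use the FSG(H/Y)G and central-C frames", {
  s <- "AAFSGHGKK"
  pk <- extractPockets(s, hPos = 6, cPos = NA)
  expect_equal(unname(pk["h_pocket"]), "FSGHG")
  expect_equal(unname(pk["c_pocket"]), "-----")

  s2 <- "QQDTCHSWW"
  pk2 <- extractPockets(s2, hPos = NA, cPos = 5)
  expect_equal(unname(pk2["c_pocket"]), "DTCHS")

  ## boundary padding: hPos = 2 leaves two '-' on the left
  pk3 <- extractPockets("AHKLM", hPos = 2, cPos = NA)
  expect_equal(unname(pk3["h_pocket"]), "--AHK")
  ## catalytic residue sits at unit 4 (H) and unit 3 (C)
  set.seed(1)
  for (k in 1:10) {
    s <- randomProtein(30)
    h <- sample(4:27, 1); c <- sample(4:27, 1)
    pk <- extractPockets(s, h, c)
    expect_equal(substr(pk[["h_pocket"]], 4, 4), substr(s, h, h))
    expect_equal(substr(pk[["c_pocket"]], 3, 3), substr(s, c, c))
  }
})

makeCalls <- function(labels, strains = "S1") {
  data.frame(
    strain_id = rep(strains, length.out = length(labels)),
    protein_id = sprintf("p%03d", seq_along(labels)),
    h_res = substr(labels, 1, 1), c_res = substr(labels, 2, 2),
    dyad_label = labels,
    oca_class = ifelse(labels == "HC", "wild_type",
                       ifelse(grepl("-", labels), "unresolved", "mutated")),
    stringsAsFactors = FALSE)
}

test_that("substitution tallies count dyads and their marginals", {
  t <- tallySubstitutions(makeCalls(c("HC", "HC", "YS")))
  expect_equal(t$dyads, c(HC = 2L, YS = 1L))
  expect_equal(t$h_site, c(H = 2L, Y = 1L))
  expect_equal(t$c_site, c(C = 2L, S = 1L))
  expect_equal(t$n_resolved, 3L)

  t2 <- tallySubstitutions(makeCalls(c("HC", "Y-", "YN")))
  expect_equal(t2$n_unresolved, 1L)
  expect_equal(sum(t2$dyads), 2L)
})

test_that("per-site marginals re-derive from per-dyad counts", {
  set.seed(21)
  labs <- c("HC", "YS", "YN", "YR", "HP", "CY")
  for (k in 1:10) {
    calls <- makeCalls(sample(labs, 40, replace = TRUE))
    t <- tallySubstitutions(calls)
    hM <- tapply(t$dyads, substr(names(t$dyads), 1, 1), sum)
    cM <- tapply(t$dyads, substr(names(t$dyads), 2, 2), sum)
    expect_equal(as.numeric(hM[names(t$h_site)]), as.numeric(t$h_site))
    expect_equal(as.numeric(cM[names(t$c_site)]), as.numeric(t$c_site))
  }
})

test_that("tallies partition by morphotype and reject unknown strains", {
  calls <- makeCalls(c("HC", "YS", "HC", "YN"), strains = c("S1", "S2"))
  md <- data.frame(strain_id = c("S1", "S2"),
                   morphotype = c("unicellular", "heterocytous"),
                   habitat = c("marine", "freshwater"),
                   proteome_size = c(3000L, 6000L))
  t <- tallySubstitutions(calls, md)
  expect_equal(t$by_morphotype$unicellular, c(HC = 2L))
  expect_equal(sort(names(t$by_morphotype$heterocytous)), c("YN", "YS"))
  calls$strain_id[1] <- "S9"
  expect_error(tallySubstitutions(calls, md), "S9")
})

test_that("degenerate consensus derivation matches the printed style", {
  cons <- deriveConsensus(c(rep("FSGHG", 6), rep("FSGYG", 4)),
                          minFreq = 0.05)
  expect_equal(cons$pattern, "FSG(H/Y)G")
  expect_equal(deriveConsensus("DTCHS")$pattern, "DTCHS")
  expect_error(deriveConsensus(character()), "no pockets")
})

test_that("consensus columns equal a brute-force frequency filter", {
  set.seed(33)
  aa <- c("A","D","F","G","H","S","T","Y")
  for (k in 1:20) {
    pockets <- replicate(50, paste(sample(aa, 5, replace = TRUE),
                                   collapse = ""))
    mf <- sample(c(0.05, 0.1, 0.3), 1)
    pat <- deriveConsensus(pockets, minFreq = mf)$pattern
    units <- regmatches(pat, gregexpr("\\([^)]*\\)|[A-Z-]", pat))[[1]]
    expect_length(units, 5)
    chars <- do.call(rbind, strsplit(pockets, ""))
    for (j in 1:5) {
      tab <- table(chars[, j]) / nrow(chars)
      keep <- names(tab)[tab >= mf]
      if (!length(keep)) keep <- names(tab)[which.max(tab)]
      got <- gsub("[()]", "", units[j])
      got <- strsplit(got, "/", fixed = TRUE)[[1]]
      expect_setequal(got, keep)
      ## ordering: descending frequency, ties alphabetical
      expect_equal(got, keep[order(-tab[keep], keep)])
    }
  }
})

test_that("a column where nothing survives keeps its modal residue", {
  pockets <- c("ASGHG", "DSGHG", "FSGHG", "GSGHG", "HSGHG")
  pat <- deriveConsensus(pockets, minFreq = 0.5)$pattern
  expect_equal(substr(pat, 1, 1), "A")  # all tie at 0.2; alphabetical modal
})

test_that("consensus matching accepts members and rejects others", {
  expect_true(matchConsensus("FSG(H/Y)G", "FSGYG"))
  expect_false(matchConsensus("FSG(H/Y)G", "FSGWG"))
  expect_false(matchConsensus("FSG(H/Y)G", "FSG-G"))  # '-' matches nothing
  expect_error(matchConsensus("FSG(H/YG", "FSGYG"), "malformed")
  expect_error(matchConsensus("FSGG", "FSGY"))
})

test_that("every contributing pocket matches its derived consensus", {
  set.seed(44)
  for (k in 1:10) {
    pockets <- replicate(30, paste(sample(c("A","D","H","S","Y"), 5,
                                          replace = TRUE), collapse = ""))
    cons <- deriveConsensus(pockets, minFreq = 1 / length(pockets))
    expect_true(all(vapply(pockets, function(p)
      matchConsensus(cons, p), TRUE)))
  }
})
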