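# k-mer miRNA encoding and the protein embedding fallback

test_that("k-mer counts match the window enumerator", {
  # hand cases
  v <- kmerEncode("AAAA", 3, normalize = TRUE)
  expect_equal(sum(v > 0), 1)
  expect_equal(v[["AAA"]], 1)
  raw <- kmerEncode("AAAA", 3, normalize = FALSE)
  expect_equal(sum(raw), 2)                      # L - k + 1 windows
  u <- kmerEncode("ACGU", 2)                     # U mapped to T
  expect_equal(sort(names(u)[u > 0]), c("AC", "CG", "GT"))
  expect_true(all(u[u > 0] == 1 / 3))
  # property: counts equal a brute-force window enumeration
  set.seed(3)
  for (rep in 1:10) {
    L <- sample(5:40, 1); k <- sample(1:4, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    got <- kmerEncode(seq, k, normalize = FALSE)
    dna <- chartr("U", "T", seq)
    windows <- substring(dna, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)
    expect_equal(length(got), 4^k)
    expect_equal(sum(got), L - k + 1)
    for (w in unique(windows))
      expect_equal(got[[w]], sum(windows == w))
  }
  expect_error(kmerEncode("ACG", 5), class = "LengthError")
  expect_error(kmerEncode("ACGX", 2), class = "AlphabetError")
})

test_that("protein fallback is a deterministic 420-dim composition code", {
  p <- proteinEncode("ACD")
  expect_length(p, 420)
  comp <- p[1:20]
  expect_equal(sum(comp), 1)
  expect_equal(unname(comp[c("A", "C", "D")]), rep(1 / 3, 3))
  expect_true(all(comp[setdiff(names(comp), c("A", "C", "D"))] == 0))
  expect_identical(p, proteinEncode("ACD"))
  # order sensitivity lives in the 2-mer block
  expect_false(isTRUE(all.equal(proteinEncode("AC"), proteinEncode("CA"))))
  # length-invariant output dimension
  expect_length(proteinEncode(paste(rep("MKT", 50), collapse = "")), 420)
  expect_length(proteinEncode("AXC"), 420)       # X tolerated
  expect_error(proteinEncode("AB1"), class = "AlphabetError")
  expect_error(proteinEncode("MKT", backend = "esm2_plugin"),
               class = "BackendUnavailableError")
})

test_that("a registered plugin backend is used verbatim", {
  registerProteinBackend("esm2_plugin", function(seq) rep(0.5, 8))
  on.exit(rm("esm2_plugin", envir = molviews:::.proteinBackends))
  v <- proteinEncode("MKT", backend = "esm2_plugin")
  expect_equal(as.numeric(v), rep(0.5, 8))
})

test_that("FASTA reading and set encoding are consistent", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">mir1 some description", "ACGUACGU",
               ">mir2", "GGGCCC"), path)
  seqs <- readFastaSequences(path)
  expect_equal(names(seqs), c("mir1", "mir2"))
  M <- kmerEncodeSet(seqs, k = 3)
  expect_equal(dim(M), c(2, 64))
  expect_equal(rownames(M), c("mir1", "mir2"))
  expect_equal(as.numeric(M["mir1", ]),
               as.numeric(kmerEncode("ACGUACGU", 3)))
})
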