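model <- default_energy_model()

test_that("the packaged energy table is legal and strand-symmetric", {
  expect_true(all(unlist(model$stacks) < 0))
  expect_gte(model$duplex_init, 0)
  expect_gte(model$bulge_open, 0)
  expect_gte(model$internal_open, 0)
  mirror <- function(key) {
    x <- strsplit(sub("/.*", "", key), "")[[1]]
    z <- strsplit(sub(".*/", "", key), "")[[1]]
    paste0(z[2], z[1], "/", x[2], x[1])
  }
  for (key in names(model$stacks)) {
    expect_equal(model$stacks[[key]], model$stacks[[mirror(key)]])
  }
})

test_that("a full Watson-Crick duplex sums initiation plus stacks", {
  d <- duplex_mfe("GGGG", "CCCC", model)
  expect_equal(d$mfe, model$duplex_init + 3 * model$stacks[["GG/CC"]])
  expect_equal(nrow(d$pairing), 4)
  expect_equal(binding_start(d), 1L)
  # antiparallel trace: miRNA ascending, target descending
  expect_equal(d$pairing$mirna_pos, 1:4)
  expect_equal(d$pairing$target_pos, 4:1)
})

test_that("unpairable sequences give mfe 0 with an empty trace", {
  d <- duplex_mfe("AAAA", "AAAA", model)
  expect_equal(d$mfe, 0)
  expect_equal(nrow(d$pairing), 0)
  expect_error(binding_start(d), "empty pairing")
})

test_that("inputs are validated", {
  expect_error(duplex_mfe("ACGT", "CCCC", model), "non-RNA")
  expect_error(duplex_mfe("A", "CCCC", model), "at least 2")
  expect_error(
    duplex_mfe("GGGG", paste(rep("C", 61), collapse = ""), model), "60"
  )
})

test_that("binding start reports the 5'-most paired miRNA base", {
  mir <- test_mirna()
  # target complementary to miRNA nt 3-10 only, embedded in unpairable A runs
  window <- substr(mir, 3, 10)
  target <- paste0("AAAAAA", mirna_from_probe(window), "AAAAAA")
  d <- duplex_mfe(mir, target, model)
  expect_equal(binding_start(d), 3L)
  expect_true(all(d$pairing$mirna_pos %in% 3:10))
})

test_that("the DP equals exhaustive enumeration on small instances", {
  # every pair over a 2-letter {G, C} alphabet up to length 4
  seqs <- unlist(lapply(2:4, function(len) {
    apply(
      expand.grid(rep(list(c("G", "C")), len)), 1, paste0,
      collapse = ""
    )
  }))
  for (a in seqs) {
    for (b in seqs) {
      expect_equal(
        duplex_mfe(a, b, model)$mfe,
        oracle_duplex_mfe(a, b, model),
        info = paste(a, b)
      )
    }
  }
  # spot checks at length 5 over the full alphabet
  set.seed(14)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "G", "U"), 5, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 5, TRUE), collapse = "")
    expect_equal(
      duplex_mfe(a, b, model)$mfe,
      oracle_duplex_mfe(a, b, model),
      info = paste(a, b)
    )
  }
})

test_that("the perfect complement is the optimal same-length partner", {
  set.seed(9)
  for (k in 1:10) {
    mir <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
    best <- duplex_mfe(mir, mirna_from_probe(mir), model)$mfe
    for (j in 1:20) {
      other <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
      expect_lte(best, duplex_mfe(mir, other, model)$mfe)
    }
  }
})

test_that("mfe is symmetric under strand exchange", {
  set.seed(10)
  for (k in 1:25) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), TRUE), collapse = "")
    expect_equal(duplex_mfe(a, b, model)$mfe, duplex_mfe(b, a, model)$mfe)
  }
})

test_that("free dangling flanks never raise the mfe", {
  set.seed(11)
  for (k in 1:15) {
    mir <- paste(sample(c("A", "C", "G", "U"), 8, TRUE), collapse = "")
    core <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    base <- duplex_mfe(mir, core, model)$mfe
    flanked <- duplex_mfe(mir, paste0("AAAA", core, "AAAA"), model)$mfe
    expect_lte(flanked, base)
  }
})

test_that("the mfe equals its own pairing trace energy", {
  set.seed(12)
  for (k in 1:20) {
    mir <- paste(sample(c("A", "C", "G", "U"), 10, TRUE), collapse = "")
    tgt <- paste(sample(c("A", "C", "G", "U"), 15, TRUE), collapse = "")
    d <- duplex_mfe(mir, tgt, model)
    if (nrow(d$pairing) == 0) next
    m <- strsplit(mir, "")[[1]]
    t <- strsplit(tgt, "")[[1]]
    e <- model$duplex_init
    for (r in seq_len(nrow(d$pairing))[-1]) {
      a <- d$pairing$mirna_pos[r] - d$pairing$mirna_pos[r - 1] - 1
      b <- d$pairing$target_pos[r - 1] - d$pairing$target_pos[r] - 1
      e <- e + if (a == 0 && b == 0) {
        model$stacks[[paste0(
          m[d$pairing$mirna_pos[r - 1]], m[d$pairing$mirna_pos[r]], "/",
          t[d$pairing$target_pos[r - 1]], t[d$pairing$target_pos[r]]
        )]]
      } else if (a == 0 || b == 0) {
        model$bulge_open + model$bulge_extend * (a + b - 1)
      } else {
        model$internal_open + model$internal_extend * (a + b - 2)
      }
    }
    expect_equal(e, d$mfe)
  }
})

test_that("site regions centre on the seed site and cap at the UTR ends", {
  utr <- paste(rep("ACGU", 25), collapse = "") # 100 nt
  r <- extract_site_region(utr, site_start = 50, site_width = 8, width = 30)
  expect_equal(nchar(r), 30)
  expect_equal(extract_site_region(utr, 1, width = 30), substr(utr, 1, 30))
})
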