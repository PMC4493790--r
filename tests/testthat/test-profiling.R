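calls_tbl <- function(scores, loci = paste0("L", seq_len(ncol(scores)))) {
  # scores: matrix samples x loci
  tibble::tibble(
    sample = rep(rownames(scores), times = ncol(scores)),
    locus = rep(loci, each = nrow(scores)),
    presence_score = as.vector(scores)
  )
}

test_that("band-ladder encoding follows the cumulative rule", {
  calls <- tibble::tibble(sample = c("A", "A", "B"),
                          locus = c("L1", "L2", "L1"),
                          presence_score = c(10, 0, 6))
  enc1 <- encode_profiles(calls, bin_width = 1)
  expect_equal(unname(enc1["A", 1:10]), rep(1L, 10))   # score 10 -> all ones
  expect_equal(unname(enc1["A", 11:20]), rep(0L, 10))  # score 0 -> all zeros

  enc2 <- encode_profiles(calls, bin_width = 2)
  expect_equal(unname(enc2["B", 1:5]), c(1L, 1L, 1L, 0L, 0L))  # score 6

  # missing score -> all-zero block
  calls$presence_score[2] <- NA
  encm <- encode_profiles(calls, bin_width = 1)
  expect_equal(sum(encm["A", 11:20]), 0)

  expect_error(encode_profiles(calls, bin_width = 3),
               class = "tedose_configuration")
})

test_that("Nei-Li distance matches hand computation and edge cases", {
  expect_equal(nei_li_dist(c(1, 1, 1, 0), c(1, 1, 1, 0)), 0)
  expect_equal(nei_li_dist(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # n_ab = 2, n_a = 3, n_b = 2 -> 1 - 4/5
  expect_equal(nei_li_dist(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.2)
  expect_error(nei_li_dist(c(0, 0), c(0, 0)),
               class = "tedose_undefined_distance")
})

test_that("matrix Nei-Li agrees with an independent Dice implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(7, {
    m <- matrix(rbinom(10 * 24, 1, 0.5), nrow = 10,
                dimnames = list(paste0("s", 1:10), NULL))
    m[rowSums(m) == 0, 1] <- 1
  })
  mine <- nei_li_dist(m)
  ref <- vegan::designdist(m, "(A+B-2*J)/(A+B)", terms = "binary")
  expect_equal(as.vector(mine), as.vector(ref), tolerance = 1e-12)
})

test_that("all-zero profiles are excluded with a warning", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), z = c(0, 0, 0))
  expect_warning(d <- nei_li_dist(m), "all-zero")
  expect_equal(attr(d, "Size"), 2)
})

test_that("UPGMA reproduces hand-computed merges and tie-breaking", {
  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.6,
                0.6, 0.6, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  m <- attr(tr, "merges")
  expect_equal(m$height, c(0.1, 0.3))
  expect_equal(attr(tr, "clades")[[1]], c("A", "B"))

  # all distances equal: first-index pair merges first, equal heights
  de <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  tre <- upgma(de)
  expect_equal(attr(tre, "clades")[[1]], c("a", "b"))
  expect_equal(attr(tre, "merges")$height, rep(0.2, 3))

  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgma(bad), class = "tedose_malformed_input")
})

test_that("UPGMA trees are ultrametric and permutation invariant", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- sample(4:8, 1)
      m <- matrix(0, n, n)
      m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 1)
      m <- m + t(m)
      dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
      tr <- upgma(m)

      depth <- max(attr(tr, "merges")$height)
      tip_depth <- ape::node.depth.edgelength(tr)[seq_len(n)]
      expect_equal(tip_depth, rep(depth, n), tolerance = 1e-9)

      # permuting the input order yields identical cophenetic distances
      p <- sample(n)
      trp <- upgma(m[p, p])
      co <- ape::cophenetic.phylo(tr)
      cop <- ape::cophenetic.phylo(trp)
      expect_equal(cop[rownames(co), colnames(co)], co, tolerance = 1e-9)
    }
  })
})

test_that("UPGMA agrees with phangorn on random matrices", {
  skip_if_not_installed("phangorn")
  withr::with_seed(77, {
    n <- 7
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 1)
    m <- m + t(m)
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  })
  tr <- upgma(m)
  ref <- phangorn::upgma(stats::as.dist(m))
  expect_equal(sort(ape::cophenetic.phylo(tr)[rownames(m), rownames(m)]),
               sort(ape::cophenetic.phylo(ref)[rownames(m), rownames(m)]),
               tolerance = 1e-9)
})

test_that("bootstrap support is 100 for duplicated-information loci", {
  withr::with_seed(5, {
    sc <- matrix(round(runif(6, 0, 10), 1), nrow = 6, ncol = 2,
                 dimnames = list(paste0("s", 1:6), NULL))
  })
  sc[, 2] <- sc[, 1]  # two identical loci: resampling cannot change anything
  tr <- bootstrap_support(calls_tbl(sc), B = 100, seed = 2)
  sup <- tidy(tr)$support
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("bootstrap with B = 1 gives all-or-nothing support", {
  withr::with_seed(6, {
    sc <- matrix(round(runif(15, 0, 10), 1), nrow = 5,
                 dimnames = list(paste0("s", 1:5), NULL))
  })
  tr <- bootstrap_support(calls_tbl(sc), B = 1, seed = 9)
  sup <- tidy(tr)$support
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("single-locus profiles have undefined support", {
  withr::with_seed(8, {
    sc <- matrix(round(runif(4, 0, 10), 1), nrow = 4,
                 dimnames = list(paste0("s", 1:4), NULL))
  })
  tr <- bootstrap_support(calls_tbl(sc), B = 10, seed = 1)
  expect_true(all(is.na(tidy(tr)$support)))
})

test_that("noisy replicates of one sample stay close in profile space", {
  # software analogue of the across-plate replicate distance check:
  # two plates of the same truth, default Ct noise, distance at bin width 1
  n_close <- 0
  n_sim <- 200
  # dosages off the band boundaries, as in real continuous ratio estimates
  truth <- tibble::tibble(sample = "R", locus = paste0("L", 1:3),
                          dosage = c(1.2, 5.3, 7.8))
  for (i in seq_len(n_sim)) {
    enc <- purrr::map(1:2, function(p) {
      scn <- plate_scenario(dosage = truth, efficiency_noise_sd_pct = 0,
                            seed = 1000 + 2 * i + p)
      calls <- simulate_plate(scn) |> estimate_reactions() |> call_dosage()
      calls$plate_sample <- paste0("R", p)
      calls
    })
    both <- dplyr::bind_rows(enc) |>
      dplyr::mutate(sample = plate_sample)
    d <- nei_li_dist(encode_profiles(both, bin_width = 1))
    if (as.vector(d)[1] < 0.05) n_close <- n_close + 1
  }
  expect_gte(n_close / n_sim, 0.95)
})

test_that("dendrograms export to Newick", {
  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(upgma(d), f)
  reread <- ape::read.tree(f)
  expect_setequal(reread$tip.label, LETTERS[1:3])
})
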