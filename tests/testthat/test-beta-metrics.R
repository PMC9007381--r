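# Frozen hand-computed values for the 3-OTU worked example
#   counts_A = (3, 1, 0), counts_B = (2, 0, 2):
# entropies H_A = -(0.75 log 0.75 + 0.25 log 0.25) = 0.5623351,
# H_B = log 2 = 0.6931472, mixture m = (0.625, 0.125, 0.25) with
# H_m = 0.9002561, so EW = 2 exp(H_m) / (exp(H_A) + exp(H_B)) = 1.3104593;
# Horn numerator 5 log 5 - 3 log 3 - 2 log 2 = 3.3650584, denominator
# 8 log 8 - 2 * 4 log 4 = 5.5451774.
worked_example <- list(
  a = c(3, 1, 0), b = c(2, 0, 2),
  jaccard = 1 / 3, sorensen = 0.5, whittaker = 1.5,
  effective_whittaker = 2 * exp(0.9002561) / (exp(0.5623351) + exp(0.6931472)),
  morisita_horn = 2 / 3, horn = 3.3650584 / 5.5451774,
  bray_curtis = 0.5, overlap = 0.625,
  # single shared OTU (index 1) after intersection-renormalization => D = 0
  dissimilarity = 0
)

test_that("identical samples give the identity bundle", {
  p <- sample_pair(c(5, 2, 0, 1), c(5, 2, 0, 1))
  m <- all_metrics(p)
  expect_equal(m$jaccard, 1)
  expect_equal(m$sorensen, 1)
  expect_equal(m$whittaker, 1)
  expect_equal(m$effective_whittaker, 1)
  expect_equal(m$morisita_horn, 1)
  expect_equal(m$horn, 1)
  expect_equal(m$bray_curtis, 0)
  expect_equal(m$dissimilarity, 0)
  expect_equal(m$overlap, 1)
})

test_that("disjoint supports give the boundary values and undefined dissimilarity", {
  p <- sample_pair(c(4, 1, 0, 0), c(0, 0, 2, 3))
  m <- all_metrics(p)
  expect_equal(m$jaccard, 0)
  expect_equal(m$sorensen, 0)
  expect_equal(m$whittaker, 2)
  expect_equal(m$morisita_horn, 0)
  expect_equal(m$horn, 0)
  expect_equal(m$bray_curtis, 1)
  expect_equal(m$overlap, 0)
  expect_true(is.na(m$dissimilarity))
  expect_identical(m$dissimilarity_reason, "empty_intersection")

  # single-read disjoint samples: the effective Whittaker exceeds 1
  p2 <- sample_pair(c(1, 0), c(0, 1))
  expect_equal(effective_whittaker(p2), 2)
})

test_that("the worked 3-OTU example matches independent hand computation", {
  p <- sample_pair(worked_example$a, worked_example$b)
  m <- all_metrics(p)
  for (nm in c("jaccard", "sorensen", "whittaker", "effective_whittaker",
               "morisita_horn", "horn", "bray_curtis", "overlap",
               "dissimilarity")) {
    expect_equal(m[[nm]], worked_example[[nm]], tolerance = 1e-6, label = nm)
  }
})

test_that("rJSD handles forced renormalization and the two-OTU hand case", {
  # single shared OTU: renormalized vectors are both (1) => zero divergence
  p1 <- sample_pair(c(3, 1, 0), c(2, 0, 2))
  expect_equal(dissimilarity_rjsd(p1), 0)

  # shared counts (3,1) vs (1,3): KL((0.75,0.25) || (0.5,0.5)) terms give
  # D = sqrt(0.75 log 1.5 + 0.25 log 0.5) = 0.3616798
  p2 <- sample_pair(c(3, 1, 0, 4), c(1, 3, 5, 0))
  expect_equal(dissimilarity_rjsd(p2), 0.3616798, tolerance = 1e-6)

  # bounded by sqrt(log 2)
  p3 <- sample_pair(c(1000, 1, 0), c(1, 1000, 0))
  expect_lt(dissimilarity_rjsd(p3), sqrt(log(2)))
})

test_that("all metrics are symmetric, permutation-invariant, and bounded", {
  withr::with_seed(31, {
    for (rep in 1:300) {
      rc <- random_count_pair()
      p <- sample_pair(rc$a, rc$b)
      m <- unlist(all_metrics(p)[1:9])

      swapped <- unlist(all_metrics(sample_pair(rc$b, rc$a))[1:9])
      expect_equal(m, swapped, tolerance = 1e-12)

      perm <- sample(length(rc$a))
      permuted <- unlist(all_metrics(sample_pair(rc$a[perm], rc$b[perm]))[1:9])
      expect_equal(m, permuted, tolerance = 1e-12)

      expect_true(all(m[c("jaccard", "sorensen", "morisita_horn", "horn",
                          "overlap", "bray_curtis")] >= 0 - 1e-12))
      expect_true(all(m[c("jaccard", "sorensen", "morisita_horn", "horn",
                          "overlap", "bray_curtis")] <= 1 + 1e-12))
      expect_gte(m[["whittaker"]], 1)
      expect_lte(m[["whittaker"]], 2)
      if (!is.na(m[["dissimilarity"]])) {
        expect_gte(m[["dissimilarity"]], 0)
        expect_lte(m[["dissimilarity"]], sqrt(log(2)) + 1e-12)
      }
    }
  })
})

test_that("metrics agree with the naive set-based oracle on random tables", {
  withr::with_seed(32, {
    for (rep in 1:500) {
      rc <- random_count_pair()
      m <- all_metrics(sample_pair(rc$a, rc$b))
      o <- oracle_metrics(rc$a, rc$b)
      for (nm in names(o)) {
        if (is.na(o[[nm]])) {
          expect_true(is.na(m[[nm]]), label = nm)
        } else {
          expect_equal(m[[nm]], o[[nm]], tolerance = 1e-12, label = nm)
        }
      }
    }
  })
})

test_that("count-based metrics agree with vegan where both define them", {
  skip_if_not_installed("vegan")
  withr::with_seed(33, {
    for (rep in 1:50) {
      rc <- random_count_pair()
      p <- sample_pair(rc$a, rc$b)
      m2 <- rbind(rc$a, rc$b)
      expect_equal(bray_curtis(p),
                   as.numeric(vegan::vegdist(m2, "bray")), tolerance = 1e-12)
      expect_equal(1 - jaccard(p),
                   as.numeric(vegan::vegdist(m2, "jaccard", binary = TRUE)),
                   tolerance = 1e-12)
      expect_equal(1 - morisita_horn(p),
                   as.numeric(vegan::vegdist(m2, "horn")), tolerance = 1e-12)
    }
  })
})

test_that("unequal read depths are supported via per-sample normalization", {
  p <- sample_pair(c(30, 10, 0), c(2, 0, 2))
  expect_equal(morisita_horn(p), 2 / 3, tolerance = 1e-12)
  expect_equal(overlap(p), 0.625, tolerance = 1e-12)
})

test_that("the long-format batch table matches per-pair calls", {
  withr::with_seed(34, {
    counts <- matrix(rpois(40, 3) * rbinom(40, 1, 0.7), nrow = 8,
                     dimnames = list(sprintf("OTU_%d", 1:8), sprintf("s%d", 1:5)))
    counts[1, ] <- counts[1, ] + 1  # no empty samples
    tab <- beta_diversity_table(counts)
    expect_equal(nrow(tab), choose(5, 2) * 9)
    one <- tab[tab$sample_A == "s1" & tab$sample_B == "s3", ]
    direct <- all_metrics(sample_pair(counts[, "s1"], counts[, "s3"]))
    for (i in seq_len(nrow(one))) {
      expect_equal(one$value[i], direct[[one$metric[i]]], tolerance = 1e-12)
    }
  })
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(sample_pair(c(0, 0), c(1, 2)), "zero")
  expect_error(sample_pair(c(1, 2, 3), c(1, 2)), "length")
  expect_error(sample_pair(c(1.5, 2), c(1, 2)), "integer")
  expect_error(sample_pair(c(-1, 2), c(1, 2)), "negative")
})
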