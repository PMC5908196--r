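emulate_hoods <- function() {
  # reference neighborhood: 5 genes either side of the focal gene f
  hood_a <- c(paste0("a", 1:5), "fa", paste0("a", 6:10))
  hood_b <- c(paste0("b", 1:5), "fb", paste0("b", 6:10))
  orthos <- data.frame(a = c(paste0("a", 1:10), "fa"),
                       b = c(paste0("b", 1:10), "fb"))
  list(hood_a = hood_a, hood_b = hood_b, orthos = orthos)
}

test_that("fully conserved flanks score 100", {
  h <- emulate_hoods()
  s <- synteny_score("fa", "fb", h$hood_a, h$hood_b, h$orthos, flank = 5)
  expect_equal(as.numeric(s), 100)
  expect_false(attr(s, "truncated"))
})

test_that("no flanking orthologs scores 0", {
  h <- emulate_hoods()
  s <- synteny_score("fa", "fb", h$hood_a, h$hood_b,
                     data.frame(a = "fa", b = "fb"), flank = 5)
  expect_equal(as.numeric(s), 0)
})

test_that("8 of 10 conserved flanks score 80 (hand-derived matching)", {
  h <- emulate_hoods()
  # break two positions: a3 and a8 have no orthologs in the window
  orthos <- h$orthos[!h$orthos$a %in% c("a3", "a8"), ]
  s <- synteny_score("fa", "fb", h$hood_a, h$hood_b, orthos, flank = 5)
  expect_equal(as.numeric(s), 80)
})

test_that("an inversion breaks order but keeps the matched remainder", {
  h <- emulate_hoods()
  hood_b <- h$hood_b
  hood_b[7:10] <- rev(hood_b[7:10])   # invert 4 genes on the 3' side
  s <- synteny_score("fa", "fb", h$hood_a, hood_b, h$orthos, flank = 5)
  # longest increasing matching: 5 left flanks + b6 + one of the inverted
  # block = 7 of 10
  expect_equal(as.numeric(s), 70)
})

test_that("synteny_score is symmetric and monotone", {
  h <- emulate_hoods()
  orthos <- h$orthos[!h$orthos$a %in% c("a2", "a9"), ]
  s_ab <- synteny_score("fa", "fb", h$hood_a, h$hood_b, orthos, 5)
  s_ba <- synteny_score("fb", "fa", h$hood_b, h$hood_a, orthos, 5)
  expect_equal(as.numeric(s_ab), as.numeric(s_ba))
  # adding back an order-consistent ortholog pair never lowers the score
  s_more <- synteny_score("fa", "fb", h$hood_a, h$hood_b,
                          rbind(orthos, data.frame(a = "a2", b = "b2")), 5)
  expect_gte(as.numeric(s_more), as.numeric(s_ab))
  # self comparison under the identity map
  self <- synteny_score("fa", "fa", h$hood_a, h$hood_a,
                        data.frame(a = h$hood_a, b = h$hood_a), 5)
  expect_equal(as.numeric(self), 100)
})

test_that("short neighborhoods are scored over available positions", {
  hood_a <- c("a1", "fa", "a2")        # only 1 gene per side
  hood_b <- c("b1", "fb", "b2")
  orthos <- data.frame(a = c("a1", "a2", "fa"), b = c("b1", "b2", "fb"))
  s <- synteny_score("fa", "fb", hood_a, hood_b, orthos, flank = 5)
  expect_equal(as.numeric(s), 100)
  expect_true(attr(s, "truncated"))
  expect_error(synteny_score("zz", "fb", hood_a, hood_b, orthos),
               "absent")
})

test_that("cluster conservation cutoff is strict", {
  expect_true(cluster_synteny_test(c(g1 = 100, g2 = 100)))
  expect_false(cluster_synteny_test(c(g1 = 80, g2 = 80)))      # exactly 80
  expect_true(cluster_synteny_test(c(g1 = 81, g2 = 81)))
  expect_error(cluster_synteny_test(numeric(0)), "empty")
})

test_that("simulated neighborhoods behave as the rates dictate", {
  sim0 <- simulate_neighborhoods(3, 30, shuffle_rate = 0, seed = 4)
  for (g in c("G2", "G3")) {
    focal_ref <- "g015"
    focal_g <- sim0$orthologs[[g]]$b[sim0$orthologs[[g]]$a == focal_ref]
    s <- synteny_score(focal_ref, focal_g, sim0$hoods$G1, sim0$hoods[[g]],
                       sim0$orthologs[[g]], flank = 5)
    expect_equal(as.numeric(s), 100)
  }
  # heavy shuffling drags scores well below 100 on average
  sim1 <- simulate_neighborhoods(6, 30, shuffle_rate = 1, seed = 4)
  scores <- vapply(names(sim1$orthologs), function(g) {
    o <- sim1$orthologs[[g]]
    if (!"g015" %in% o$a) return(NA_real_)
    as.numeric(synteny_score("g015", o$b[o$a == "g015"], sim1$hoods$G1,
                             sim1$hoods[[g]], o, flank = 5))
  }, numeric(1))
  expect_lt(mean(scores, na.rm = TRUE), 80)
  # determinism
  sim0b <- simulate_neighborhoods(3, 30, shuffle_rate = 0, seed = 4)
  expect_identical(sim0, sim0b)
})
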