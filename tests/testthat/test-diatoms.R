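test_that("relative abundance and square-root standardisation", {
  m <- matrix(c(250, 250, 4, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("0", "1", "2"), c("A", "B")))
  p <- relative_abundance(m)
  expect_equal(unname(p[1, ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-12)
  tr <- transform_standardize(m)
  expect_equal(unname(tr[2, ]), c(1, 0))
  expect_equal(unname(tr[3, ]), c(sqrt(0.5), sqrt(0.5)))
  # the transform must not be applied twice: re-applying it to already
  # transformed (non-degenerate) data changes the values
  uneven <- matrix(c(4, 1, 2, 8), nrow = 2,
                   dimnames = list(c("0", "1"), c("A", "B")))
  tu <- transform_standardize(uneven)
  expect_false(isTRUE(all.equal(transform_standardize(tu), tu)))
  bad <- m; bad[2, ] <- 0
  expect_error(relative_abundance(bad), "zero-count slice")
})

test_that("Bray-Curtis matches the hand formula and satisfies its axioms", {
  u <- c(1, 1, 0); v <- c(0, 1, 1)
  d <- bray_curtis(rbind(u, v))
  expect_equal(as.numeric(d), 0.5)
  expect_equal(as.numeric(bray_curtis(rbind(u, u))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 2)))), 1)
  # hand formula cross-check on random matrices
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(rpois(24, 5), nrow = 4)
    d <- as.matrix(bray_curtis(m))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_true(all(d >= 0 & d <= 1))
    bc <- function(a, b) 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))
    expect_equal(d[1, 2], bc(m[1, ], m[2, ]))
    expect_equal(d[3, 4], bc(m[3, ], m[4, ]))
  }
  expect_error(bray_curtis(matrix(1, 1, 3)), ">= 2")
  expect_error(bray_curtis(rbind(c(-1, 0), c(1, 1))), "negative")
})

test_that("group-average clustering agglomerates like the hand example", {
  d <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["A", "C"] <- d["C", "A"] <- 0.6
  d["B", "C"] <- d["C", "B"] <- 0.8
  hc <- cluster_group_average(d, labels = LETTERS[1:3])
  expect_equal(hc$height, c(0.2, 0.7))   # (A,B) at 0.2, then C at (0.6+0.8)/2
  expect_true(are_siblings(hc, "A", "B"))
  expect_true(all(diff(hc$height) >= 0))
  # identical samples merge at height zero
  m <- rbind(a = c(3, 1), b = c(3, 1), c = c(0, 9))
  hc0 <- cluster_group_average(bray_curtis(m), labels = rownames(m))
  expect_equal(min(hc0$height), 0)
  expect_error(cluster_group_average(matrix(1, 2, 3)), "square")
})

test_that("surface/bottom pairs cluster as siblings on paired communities", {
  m <- paired_communities(n_lakes = 10, seed = 3)
  hc <- cluster_group_average(bray_curtis(transform_standardize(m)),
                              labels = rownames(m))
  sib <- vapply(1:10, function(l) {
    are_siblings(hc, paste0("L", l, "_s"), paste0("L", l, "_b"))
  }, logical(1))
  expect_gte(sum(sib), 8)
})

test_that("top/bottom screen flags indicator appearance, not stasis", {
  taxa <- c("Asterionella formosa", "Fragilaria crotonensis")
  mk <- function(top_ind, bot_ind, total = 500) {
    m <- rbind(c(top_ind, total - top_ind), c(bot_ind, total - bot_ind))
    dimnames(m) <- list(c("0", "10"), c(taxa[1], "other"))
    m
  }
  expect_warning(scr <- top_bottom_screen(mk(200, 0), taxa), "absent")
  expect_true(scr$flag)      # 40% at top, absent at bottom
  expect_warning(scr0 <- top_bottom_screen(mk(0, 0), taxa), "absent")
  expect_false(scr0$flag)    # absent everywhere
  expect_warning(scr6 <- top_bottom_screen(mk(30, 30), taxa), "absent")
  expect_false(scr6$flag)    # 6% in both: no increase
})

test_that("shift detection walks the doubling-plus-5-percent rule", {
  mk_counts <- function(props, total = 1000) {
    m <- cbind(round(props * total), total - round(props * total))
    dimnames(m) <- list(format(seq_len(length(props)) - 1),
                        c("Asterionella formosa", "other"))
    m
  }
  am <- data.frame(slice_top_cm = 0:4, date = c(2000, 1990, 1980, 1970, 1960),
                   date_sd = rep(1, 5))
  # bottom->top (0.01, 0.01, 0.02, 0.06, 0.12); background = deepest 2 slices
  props <- c(0.12, 0.06, 0.02, 0.01, 0.01)   # rows run surface -> deep
  sh <- detect_shift(mk_counts(props), am, taxa = "Asterionella formosa",
                     background_n = 2)
  expect_equal(sh$shift_depth_cm, 1)         # the 0.06 slice
  expect_equal(sh$threshold, 0.05)           # max(2*0.01, 0.05)
  expect_equal(sh$shift_date, 1990)
  # window: bottom boundary of the slice below the trigger, up to the
  # trigger date, each widened by 1 sd
  expect_equal(sh$window, c(1970 - 1, 1990 + 1))

  # all zeros: nothing fires
  expect_null(detect_shift(mk_counts(rep(0, 5)), am,
                           taxa = "Asterionella formosa", background_n = 2))

  # doubling clause binds: background 0.04, rise to 0.07 < 0.08
  props2 <- c(0.07, 0.06, 0.05, 0.04, 0.04)
  expect_null(detect_shift(mk_counts(props2), am,
                           taxa = "Asterionella formosa", background_n = 2))

  expect_error(detect_shift(mk_counts(props)[1:3, ], am,
                            taxa = "Asterionella formosa"), ">= 4")
})

test_that("shift detection ignores added taxa that stay below 1 percent", {
  scn <- core_scenario()
  core <- gen_sediment_core(scn, 2009, seed = 21)
  am <- crs_ages(core$profile, 2009)
  dia <- gen_diatom_core(scn, core$truth, seed = 21)
  base <- detect_shift(dia$counts, am, taxa = indicator_taxa(extended = TRUE))
  rare <- cbind(dia$counts,
                "rare sp." = rep(3, nrow(dia$counts)))  # < 1% of >= 500
  with_rare <- detect_shift(rare, am, taxa = indicator_taxa(extended = TRUE))
  expect_equal(with_rare$shift_depth_cm, base$shift_depth_cm)
  expect_equal(with_rare$triggered_by, base$triggered_by)
})
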