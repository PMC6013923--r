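# minimal hand-built flux_samples object for statistics tests
fake_samples <- function(mat, diet = NULL) {
  structure(list(samples = mat, reaction_ids = rownames(mat), diet = diet,
                 config = NULL, dim = NA,
                 validity = list(max_steady_state_residual = 0,
                                 max_bound_violation = 0)),
            class = "flux_samples")
}

test_that("flux summaries use type-7 quartiles", {
  m <- rbind(const = rep(2.5, 7), count = as.numeric(1:7))
  fs <- fake_samples(m)
  s <- summarize_fluxes(fs, c("const", "count"))
  expect_equal(s$median, c(2.5, 4))
  expect_equal(s$q1, c(2.5, 2.5))
  expect_equal(s$q3, c(2.5, 5.5))
  expect_error(summarize_fluxes(fs, "nope"), "not in sample set")

  withr::with_seed(8, {
    x <- stats::rlnorm(501)
    fs2 <- fake_samples(rbind(x = x))
    s2 <- summarize_fluxes(fs2, "x")
    expect_equal(s2$median, quantile7_oracle(x, 0.5))
    expect_equal(s2$q1, quantile7_oracle(x, 0.25))
    expect_equal(s2$q3, quantile7_oracle(x, 0.75))
  })
})

test_that("a clearly shifted group earns its own letter", {
  withr::with_seed(21, {
    g <- lapply(c(0, 0, 10), function(mu)
      fake_samples(rbind(v = stats::rnorm(100, mu, 1))))
    names(g) <- c("A", "B", "C")
    cmp <- compare_groups(g, "v")
    expect_lt(cmp$anova_p, 1e-10)
    # A and B share a letter, C shares none with them
    shares <- function(a, b) {
      any(strsplit(cmp$letters[[a]], "")[[1]] %in%
            strsplit(cmp$letters[[b]], "")[[1]])
    }
    expect_true(shares("A", "B"))
    expect_false(shares("A", "C"))
    expect_false(shares("B", "C"))
  })
})

test_that("identical constant groups share a letter with p = 1", {
  g <- list(A = fake_samples(rbind(v = rep(1, 10))),
            B = fake_samples(rbind(v = rep(1, 10))))
  cmp <- compare_groups(g, "v")
  expect_identical(unname(cmp$letters["A"]), unname(cmp$letters["B"]))
  expect_equal(cmp$anova_p, 1)

  g2 <- list(A = fake_samples(rbind(v = rep(1, 10))),
             B = fake_samples(rbind(v = rep(2, 10))))
  cmp2 <- compare_groups(g2, "v")
  expect_false(cmp2$letters["A"] == cmp2$letters["B"])
})

test_that("two-group ANOVA equals the squared t statistic", {
  withr::with_seed(5, {
    x <- stats::rnorm(40); y <- stats::rnorm(35, 0.4)
    g <- list(A = fake_samples(rbind(v = x)), B = fake_samples(rbind(v = y)))
    cmp <- compare_groups(g, "v")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(cmp$anova_F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(cmp$anova_p, tt$p.value, tolerance = 1e-10)
  })
})

test_that("letter display is consistent with the significance matrix", {
  withr::with_seed(33, {
    for (rep in 1:40) {
      k <- sample(3:6, 1)
      sig <- matrix(FALSE, k, k)
      pairs <- which(upper.tri(sig), arr.ind = TRUE)
      on <- stats::runif(nrow(pairs)) < 0.4
      for (i in seq_len(nrow(pairs))) {
        sig[pairs[i, 1], pairs[i, 2]] <- sig[pairs[i, 2], pairs[i, 1]] <- on[i]
      }
      rownames(sig) <- colnames(sig) <- paste0("g", seq_len(k))
      let <- mitoflux:::compact_letter_display(sig)
      expect_true(all(nzchar(let)))
      for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
        share <- any(strsplit(let[i], "")[[1]] %in% strsplit(let[j], "")[[1]])
        if (sig[i, j]) {
          expect_false(share, label = paste("rep", rep, i, j, "separate"))
        } else {
          expect_true(share, label = paste("rep", rep, i, j, "share"))
        }
      }
    }
  })
})

test_that("letters agree with the multcomp compact letter display", {
  withr::with_seed(61, {
    flux <- c(stats::rnorm(60, 0), stats::rnorm(60, 0.2), stats::rnorm(60, 2))
    grp <- factor(rep(c("A", "B", "C"), each = 60))
    g <- split(flux, grp)
    sets <- lapply(g, function(v) fake_samples(rbind(v = v)))
    cmp <- compare_groups(sets, "v")

    fit <- stats::aov(flux ~ grp)
    cld_ref <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(grp = "Tukey")))
    ref <- cld_ref$mcletters$Letters
    # same sharing structure (letter names may differ)
    for (i in 1:2) for (j in (i + 1):3) {
      share_ours <- any(strsplit(cmp$letters[i], "")[[1]] %in%
                          strsplit(cmp$letters[j], "")[[1]])
      share_ref <- any(strsplit(ref[i], "")[[1]] %in%
                         strsplit(ref[j], "")[[1]])
      expect_identical(share_ours, share_ref)
    }
  })
})

test_that("pearson correlation handles exact collinearity and simulation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
  expect_error(pearson_correlation(1:2, 2:1), "at least 3")

  withr::with_seed(17, {
    n <- 1000; rho <- 0.6
    a <- stats::rnorm(n)
    b <- rho * a + sqrt(1 - rho^2) * stats::rnorm(n)
    r <- pearson_correlation(a, b)
    expect_true(r$ci95[1] <= rho && rho <= r$ci95[2])
    expect_lt(r$p, 1e-10)
  })
})

test_that("group comparisons validate their inputs", {
  g1 <- list(A = fake_samples(rbind(v = 1:10)))
  expect_error(compare_groups(g1, "v"), "at least two")
  g2 <- list(A = fake_samples(rbind(v = 1:10)),
             B = fake_samples(rbind(w = 1:10)))
  expect_error(compare_groups(g2, "v"), "not present")
})
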