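#' Per-reaction flux summaries (median and quartiles)
#'
#' Quartiles use the linear-interpolation convention (R's default type 7),
#' matching the boxplot statistics reported for the sampled fluxes.
#'
#' @param samples A `"flux_samples"` object.
#' @param reactions Reaction ids to summarize.
#' @return Data frame with columns `reaction`, `median`, `q1`, `q3`.
#' @export
summarize_fluxes <- function(samples, reactions = samples$reaction_ids) {
  stopifnot(inherits(samples, "flux_samples"))
  missing <- setdiff(reactions, samples$reaction_ids)
  if (length(missing)) {
    stop("reaction(s) not in sample set: ", paste(missing, collapse = ", "))
  }
  qs <- t(apply(samples$samples[reactions, , drop = FALSE], 1,
                stats::quantile, probs = c(0.5, 0.25, 0.75),
                names = FALSE, type = 7))
  data.frame(reaction = reactions,
             median = qs[, 1], q1 = qs[, 2], q3 = qs[, 3],
             row.names = NULL)
}

# Compact letter display by insert-and-absorb on a significance matrix.
# sig[i, j] TRUE means groups i and j differ; returns one letter string per
# group such that groups sharing any letter are not significantly different
# and groups sharing none are. Ties are broken by group order as supplied.
compact_letter_display <- function(sig, group_names = rownames(sig)) {
  k <- nrow(sig)
  classes <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!sig[i, j]) next
      out <- list()
      for (cl in classes) {
        if (i %in% cl && j %in% cl) {
          out <- c(out, list(setdiff(cl, i)), list(setdiff(cl, j)))
        } else {
          out <- c(out, list(cl))
        }
      }
      # absorb classes contained in another class
      keep <- rep(TRUE, length(out))
      for (a in seq_along(out)) {
        for (b in seq_along(out)) {
          if (a != b && keep[b] &&
              all(out[[a]] %in% out[[b]]) &&
              (length(out[[a]]) < length(out[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      classes <- out[keep]
    }
  }
  classes <- classes[order(vapply(classes, min, 1L))]
  letters_out <- character(k)
  for (c_idx in seq_along(classes)) {
    for (g in classes[[c_idx]]) {
      letters_out[g] <- paste0(letters_out[g], letters[c_idx])
    }
  }
  stats::setNames(letters_out, group_names)
}

#' Cross-diet comparison of sampled fluxes through one reaction
#'
#' One-way ANOVA across the sample sets followed by Tukey-Kramer
#' honestly-significant-difference post hoc comparisons (exact for
#' unequal group sizes via [stats::TukeyHSD()]), with a compact letter
#' display: groups sharing a letter do not differ at level `alpha`.
#' Letters are keyed to the comparison of means; medians and quartiles are
#' reported alongside for the boxplot view. Sampled fluxes are treated as
#' independent observations, replicating the original study procedure; note that
#' chain autocorrelation inflates effective significance, so an optional
#' thinning factor is provided.
#'
#' @param sample_sets List of `"flux_samples"` objects (one per diet); names
#'   default to their diet labels.
#' @param reaction_id Reaction to compare.
#' @param alpha Significance level for the letter display.
#' @param thin Keep every `thin`-th sample point (1 = all).
#' @return An object of class `"group_comparison"`.
#' @export
compare_groups <- function(sample_sets, reaction_id, alpha = 0.05, thin = 1L) {
  if (length(sample_sets) < 2) {
    stop("at least two sample sets are required for a group comparison")
  }
  labels <- names(sample_sets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(seq_along(sample_sets), function(k) {
      d <- sample_sets[[k]]$diet
      if (is.null(d)) paste0("group", k) else d
    }, "")
  }
  values <- lapply(sample_sets, function(ss) {
    if (!reaction_id %in% ss$reaction_ids) {
      stop("reaction '", reaction_id, "' not present in all sample sets")
    }
    v <- ss$samples[reaction_id, ]
    v[seq(1, length(v), by = thin)]
  })
  if (any(lengths(values) < 2)) {
    stop("each group needs at least two sample points")
  }

  flux <- unlist(values, use.names = FALSE)
  group <- factor(rep(labels, lengths(values)), levels = labels)

  if (all(vapply(values, stats::var, 0) == 0)) {
    # degenerate: constant within every group
    eq <- length(unique(vapply(values, `[`, 0, 1))) == 1L
    sig <- matrix(!eq, length(labels), length(labels),
                  dimnames = list(labels, labels))
    diag(sig) <- FALSE
    fit_F <- NA_real_
    fit_p <- if (eq) 1 else 0
    pw <- ifelse(sig, 0, 1)
  } else {
    fit <- stats::aov(flux ~ group)
    at <- summary(fit)[[1]]
    fit_F <- at$`F value`[1]
    fit_p <- at$`Pr(>F)`[1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    pw <- matrix(1, length(labels), length(labels),
                 dimnames = list(labels, labels))
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pairs)) {
      a <- pairs[[r]][1]; b <- pairs[[r]][2]
      pw[a, b] <- pw[b, a] <- tk[r, "p adj"]
    }
    sig <- pw < alpha
  }

  qs <- vapply(values, stats::quantile, numeric(3),
               probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(reaction_id = reaction_id,
         group_labels = labels,
         n = lengths(values),
         means = vapply(values, mean, 0),
         medians = stats::setNames(qs[2, ], labels),
         q1 = stats::setNames(qs[1, ], labels),
         q3 = stats::setNames(qs[3, ], labels),
         anova_F = fit_F,
         anova_p = fit_p,
         tukey_pairwise = pw,
         letters = compact_letter_display(sig, labels),
         alpha = alpha),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat("Cross-diet comparison of ", x$reaction_id,
      " (one-way ANOVA F = ", format(x$anova_F, digits = digits),
      ", p = ", format(x$anova_p, digits = digits),
      "; Tukey-Kramer letters at alpha = ", x$alpha, ")\n", sep = "")
  print(data.frame(group = x$group_labels, n = x$n,
                   median = signif(x$medians, digits),
                   q1 = signif(x$q1, digits), q3 = signif(x$q3, digits),
                   mean = signif(x$means, digits),
                   letters = x$letters, row.names = NULL))
  invisible(x)
}

#' Pearson correlation with test and confidence interval
#'
#' Sample Pearson correlation, two-sided p value from the t transform, and
#' 95% confidence interval via the Fisher z transform.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return List with `r`, `p`, `ci95` (length-2 vector; `NA` for n = 3).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired observations are required")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate),
       p = ct$p.value,
       ci95 = if (is.null(ct$conf.int)) c(NA_real_, NA_real_)
              else as.numeric(ct$conf.int))
}
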