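#' Compare quantification methods by ANOVA with variance-aware post hoc tests
#'
#' The standard agreement test between groups of replicate measurements
#' (e.g. marker-gene qPCR vs sequencing-derived estimates of the same
#' spike-in): homogeneity of variances is checked with Levene's test
#' (mean-centered); if variances are homogeneous at `alpha`, a one-way ANOVA
#' with Tukey's honestly-significant-difference pairwise comparisons is
#' used, otherwise Tamhane's T2 (pairwise Welch t tests with Sidak
#' adjustment), which does not assume equal variances. Groups are then
#' assigned a compact letter display: groups sharing a letter are not
#' significantly different.
#'
#' @param data Data frame of replicate measurements.
#' @param group,value Column names (strings) of the grouping factor and the
#'   measured value. Defaults `"group"` and `"value"`.
#' @param alpha Significance level for both the variance test and the
#'   pairwise comparisons.
#' @return A `method_comparison` object: `levene_p`, `method` (`"tukey"` or
#'   `"tamhane"`), `pairwise` tibble (`group1`, `group2`, `estimate`,
#'   `p_adj`), and `letters` tibble (`group`, `mean`, `letters`), ordered by
#'   decreasing group mean. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
#'                 value = c(1, 1.1, 0.9, 5, 5.2, 4.9, 9, 9.1, 8.8))
#' compare_methods_anova(d)
compare_methods_anova <- function(data, group = "group", value = "value",
                                  alpha = 0.05) {
  if (!is.data.frame(data) || !all(c(group, value) %in% names(data))) {
    abort(sprintf("`data` needs columns '%s' and '%s'", group, value))
  }
  g <- factor(data[[group]])
  y <- data[[value]]
  if (anyNA(y)) abort("missing values in the measurements")
  sizes <- table(g)
  if (length(sizes) < 2L) abort("need at least 2 groups")
  if (any(sizes < 2L)) {
    abort(sprintf("group '%s' has fewer than 2 replicates", names(sizes)[sizes < 2L][1L]))
  }
  lev <- car::leveneTest(y ~ g, center = mean)
  levene_p <- lev[["Pr(>F)"]][1L]
  if (is.finite(levene_p) && levene_p < alpha) {
    method <- "tamhane"
    pairwise <- tamhane_t2(y, g)
  } else {
    method <- "tukey"
    tk <- TukeyHSD(aov(y ~ g))$g
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble(
      group1 = purrr::map_chr(pairs, 1L),
      group2 = purrr::map_chr(pairs, 2L),
      estimate = unname(tk[, "diff"]),
      p_adj = unname(tk[, "p adj"])
    )
  }
  letters <- letter_display(levels(g), pairwise, tapply(y, g, mean), alpha)
  structure(
    list(levene_p = levene_p, method = method, alpha = alpha,
         pairwise = pairwise, letters = letters),
    class = "method_comparison"
  )
}

# Tamhane's T2: pairwise Welch t statistics with Welch-Satterthwaite degrees
# of freedom and Sidak-style adjustment over the m comparisons.
tamhane_t2 <- function(y, g) {
  lev <- levels(g)
  m <- choose(length(lev), 2L)
  stats <- tapply(y, g, function(v) c(mean(v), stats::var(v), length(v)))
  out <- purrr::map(utils::combn(lev, 2L, simplify = FALSE), function(p) {
    a <- stats[[p[1L]]]; b <- stats[[p[2L]]]
    se2 <- a[2L] / a[3L] + b[2L] / b[3L]
    tt <- (a[1L] - b[1L]) / sqrt(se2)
    df <- se2^2 / ((a[2L] / a[3L])^2 / (a[3L] - 1) + (b[2L] / b[3L])^2 / (b[3L] - 1))
    p_raw <- if (se2 == 0) as.numeric(a[1L] == b[1L]) else 2 * pt(-abs(tt), df)
    tibble(group1 = p[1L], group2 = p[2L], estimate = a[1L] - b[1L],
           p_adj = min(1, 1 - (1 - p_raw)^m))
  })
  bind_rows(out)
}

# Compact letter display by insert-and-absorb: start with one column holding
# every group; for each significantly different pair sharing a column, split
# the column; absorb columns that became subsets of others. Groups are
# processed in decreasing-mean order, so the lettering is invariant to the
# input row order.
letter_display <- function(groups, pairwise, means, alpha) {
  ord <- order(-means[groups], groups)
  groups <- groups[ord]
  k <- length(groups)
  cols <- list(rep(TRUE, k))
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairwise))) {
    if (isTRUE(pairwise$p_adj[i] < alpha)) {
      sig[pairwise$group1[i], pairwise$group2[i]] <- TRUE
      sig[pairwise$group2[i], pairwise$group1[i]] <- TRUE
    }
  }
  for (a in seq_len(k - 1L)) {
    for (b in seq((a + 1L), k)) {
      if (!sig[a, b]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[a] && col[b]) {
          c1 <- col; c1[b] <- FALSE
          c2 <- col; c2[a] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      keep <- !purrr::map_lgl(seq_along(cols), function(i) {
        any(purrr::map_lgl(seq_along(cols), function(j) {
          i != j && all(cols[[i]] <= cols[[j]]) && any(cols[[i]] < cols[[j]])
        })) || any(purrr::map_lgl(seq_len(i - 1L), function(j) {
          identical(cols[[i]], cols[[j]])
        }))
      })
      cols <- cols[keep]
    }
  }
  first_member <- purrr::map_int(cols, ~ which(.x)[1L])
  cols <- cols[order(first_member)]
  lab <- purrr::map_chr(seq_len(k), function(i) {
    paste(letters[which(purrr::map_lgl(cols, ~ .x[i]))], collapse = "")
  })
  tibble(group = groups, mean = unname(means[groups]), letters = lab)
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Levene p = %.4g -> %s post hoc (alpha = %s)\n",
              x$levene_p, x$method, format(x$alpha)))
  print(x$letters, ...)
  invisible(x)
}
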