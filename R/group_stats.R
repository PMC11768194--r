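## Group comparison statistics behind the lettered tables: mean +/- SD,
## one-way ANOVA, Tukey HSD (Tukey-Kramer when unbalanced) and the
## compact letter display (insert-and-absorb).

#' Grouped replicate data
#'
#' @param group group labels (>= 2 groups).
#' @param value numeric, finite replicate values (>= 2 per group for
#'   inference).
#' @return an object of class `group_data`.
#' @export
group_data <- function(group, value) {
  if (length(group) != length(value)) {
    abort("group and value must have equal length", "crumblab_bad_arg")
  }
  if (!all(is.finite(value))) {
    abort("values must be numeric and finite", "crumblab_bad_arg")
  }
  group <- factor(group)
  if (nlevels(group) < 2L) abort("need >= 2 groups", "crumblab_bad_arg")
  if (any(table(group) < 2L)) {
    abort("need >= 2 replicates per group", "crumblab_bad_arg")
  }
  structure(list(group = group, value = as.numeric(value)),
            class = "group_data")
}

as_group_data <- function(x, ...) {
  if (inherits(x, "group_data")) x else group_data(x$group, x$value)
}

group_decomposition <- function(data) {
  g <- data$group; y <- data$value
  k <- nlevels(g); n <- length(y)
  ni <- as.numeric(table(g))
  means <- tapply(y, g, mean)
  ss_between <- sum(ni * (means - mean(y))^2)
  ss_within <- sum((y - means[g])^2)
  df1 <- k - 1L; df2 <- n - k
  list(k = k, n = n, ni = ni, means = means, ss_between = ss_between,
       ss_within = ss_within, df1 = df1, df2 = df2,
       mse = ss_within / df2)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition. When every group has zero
#' within-group variance the F statistic is degenerate: a warning is
#' emitted and p is reported as 0 when the group means differ (the
#' difference is then exact), or 1 when all observations are identical.
#'
#' @param data a [group_data()] (or a list/data.frame with `group` and
#'   `value`).
#' @return list with `f`, `p`, `df1`, `df2`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(data) {
  data <- as_group_data(data)
  d <- group_decomposition(data)
  if (d$ss_within <= 0) {
    warning("degenerate ANOVA: zero within-group variance in every group",
            call. = FALSE)
    p <- if (d$ss_between > 0) 0 else 1
    return(list(f = NA_real_, p = p, df1 = d$df1, df2 = d$df2,
                ss_between = d$ss_between, ss_within = d$ss_within))
  }
  f <- (d$ss_between / d$df1) / d$mse
  list(f = f, p = pf(f, d$df1, d$df2, lower.tail = FALSE),
       df1 = d$df1, df2 = d$df2,
       ss_between = d$ss_between, ss_within = d$ss_within)
}

## Tukey HSD adjusted p for one pair (Tukey-Kramer standard error)
tukey_pairwise <- function(d) {
  combs <- utils::combn(d$k, 2L)
  lev <- names(d$means)
  apply(combs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    diff <- d$means[j] - d$means[i]
    se <- sqrt(d$mse / 2 * (1 / d$ni[i] + 1 / d$ni[j]))
    if (se == 0) {
      p <- if (diff == 0) 1 else 0
      q <- if (diff == 0) 0 else Inf
    } else {
      q <- abs(diff) / se
      p <- ptukey(q, nmeans = d$k, df = d$df2, lower.tail = FALSE)
    }
    data.frame(group1 = lev[i], group2 = lev[j], diff = unname(diff),
               q = unname(q), p_adj = unname(p), stringsAsFactors = FALSE)
  }) |> do.call(what = rbind)
}

## insert-and-absorb compact letter display over a significance matrix
## sig[i, j] TRUE means groups i and j differ; groups ordered as given.
## Returns one letter string per group such that two groups share a
## letter iff they do NOT differ.
letters_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))  # letter columns: membership vectors
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i || !sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          ## duplicate the column, drop i from one copy and j from the other
          col_a <- col; col_a[i] <- FALSE
          col_b <- col; col_b[j] <- FALSE
          cols[[ci]] <- col_a
          cols[[length(cols) + 1L]] <- col_b
        }
      }
      ## absorb: drop columns whose membership is a subset of another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]])) {
            keep[a] <- FALSE
          }
        }
      }
      ## also drop exact duplicates
      if (any(keep)) {
        sigs <- vapply(cols, function(cc) paste(as.integer(cc), collapse = ""), "")
        keep <- keep & !duplicated(sigs)
      }
      cols <- cols[keep]
    }
  }
  ## order columns by first member so "a" goes to the highest-ranked group
  first <- vapply(cols, function(cc) which(cc)[1L], 0L)
  cols <- cols[order(first)]
  vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cc) cc[i], TRUE))], collapse = "")
  }, "")
}

#' Tukey HSD with compact letter display
#'
#' All pairwise comparisons with studentized-range adjusted p values
#' (Tukey-Kramer standard errors when group sizes differ) and a compact
#' letter display: letters are assigned by insert-and-absorb so that two
#' groups share at least one letter if and only if their adjusted p is
#' `>= alpha`. Letters are ordered by descending group mean ("a" =
#' highest), matching the usual table style.
#'
#' @param data a [group_data()].
#' @param alpha significance level (default 0.05).
#' @return list of class `tukey_outcome`: `pairs` (data.frame with
#'   `group1`, `group2`, `diff`, `q`, `p_adj`), `letters` (named character
#'   vector, one string per group), `means`, `alpha`.
#' @export
tukey_letters <- function(data, alpha = 0.05) {
  data <- as_group_data(data)
  check_number(alpha, "alpha", min = 1e-12, max = 1 - 1e-12)
  d <- group_decomposition(data)
  if (d$ss_within <= 0) {
    warning("degenerate Tukey test: zero within-group variance in every group",
            call. = FALSE)
  }
  pairs <- tukey_pairwise(d)
  ## order groups by descending mean for lettering
  ord <- order(d$means, decreasing = TRUE)
  lev <- names(d$means)[ord]
  sig <- matrix(FALSE, d$k, d$k, dimnames = list(lev, lev))
  for (r in seq_len(nrow(pairs))) {
    if (pairs$p_adj[r] < alpha) {
      sig[pairs$group1[r], pairs$group2[r]] <- TRUE
      sig[pairs$group2[r], pairs$group1[r]] <- TRUE
    }
  }
  lets <- letters_insert_absorb(sig)
  names(lets) <- lev
  structure(list(pairs = pairs, letters = lets[names(d$means)],
                 means = d$means, alpha = alpha),
            class = "tukey_outcome")
}

#' @export
print.tukey_outcome <- function(x, ...) {
  cat(sprintf("<tukey_outcome> alpha = %g\n", x$alpha))
  tab <- data.frame(group = names(x$means), mean = as.numeric(x$means),
                    letters = unname(x$letters))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Mean +/- SD summary with significance letters
#'
#' The table format used in composite-flour studies: per-group mean,
#' standard deviation and Tukey letter for one measured variable.
#'
#' @param data a [group_data()].
#' @param alpha significance level for the letters.
#' @param digits rounding for the formatted `mean_sd` column.
#' @return data.frame with `group`, `n`, `mean`, `sd`, `letters`,
#'   `mean_sd` (formatted string).
#' @export
lettered_table <- function(data, alpha = 0.05, digits = 2) {
  data <- as_group_data(data)
  tk <- tukey_letters(data, alpha)
  means <- tapply(data$value, data$group, mean)
  sds <- tapply(data$value, data$group, sd)
  ns <- as.integer(table(data$group))
  data.frame(
    group = names(means), n = ns, mean = as.numeric(means),
    sd = as.numeric(sds), letters = unname(tk$letters[names(means)]),
    mean_sd = sprintf(paste0("%.", digits, "f ± %.", digits, "f %s"),
                      means, sds, tk$letters[names(means)]),
    stringsAsFactors = FALSE
  )
}
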