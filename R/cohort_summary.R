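#' Standardized difference between two categorical distributions
#'
#' For a binary variable the conventional two-proportion formula
#' |p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2) is used. For k > 2
#' categories the Mahalanobis-type multivariate standardized difference is
#' computed over the first k - 1 categories with the averaged multinomial
#' covariance matrix. Symmetric in its arguments; zero iff the
#' distributions are identical.
#'
#' @param p1,p2 Proportion vectors of equal length (each summing to 1,
#'   tolerance 1e-8, length >= 2).
#' @return A non-negative scalar.
#' @export
standardized_difference <- function(p1, p2) {
  if (length(p1) != length(p2) || length(p1) < 2) {
    stop("`p1` and `p2` must have equal length >= 2")
  }
  if (abs(sum(p1) - 1) > 1e-8 || abs(sum(p2) - 1) > 1e-8) {
    stop("proportion vectors must each sum to 1")
  }
  if (all(abs(p1 - p2) < .Machine$double.eps * 4)) return(0)
  if (length(p1) == 2) {
    v <- (p1[1] * (1 - p1[1]) + p2[1] * (1 - p2[1])) / 2
    return(abs(p1[1] - p2[1]) / sqrt(v))
  }
  k <- length(p1)
  d <- (p1 - p2)[-k]
  S <- matrix(0, k - 1, k - 1)
  for (i in seq_len(k - 1)) for (j in seq_len(k - 1)) {
    S[i, j] <- if (i == j) (p1[i] * (1 - p1[i]) + p2[i] * (1 - p2[i])) / 2
               else -(p1[i] * p1[j] + p2[i] * p2[j]) / 2
  }
  sol <- tryCatch(solve(S, d), error = function(e) {
    # near-singular covariance: fall back to a pseudo-inverse
    ev <- eigen(S, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      ((crossprod(ev$vectors[, pos, drop = FALSE], d)) / ev$values[pos])
  })
  sqrt(max(sum(d * sol), 0))
}

#' Categorical summary of one variable in one or two cohorts
#'
#' Exact counts and percentages per category; with two cohorts the
#' standardized difference is attached. Percentages are carried at full
#' precision; rounding is applied only by the print method (one decimal by
#' default, two for the sensitization-category block as conventionally
#' printed).
#'
#' @param records Registrant records for cohort A.
#' @param variable Covariate name: one of `age_group`, `gender`, `abo`,
#'   `race`, `esrd_diagnosis`, or `pra_category` (derived from the initial
#'   CPRA).
#' @param records_b Optional cohort-B records.
#' @param categories CPRA category table (for `pra_category`).
#' @return A data frame of class `msm_categorical_summary`.
#' @export
summarize <- function(records, variable, records_b = NULL,
                      categories = cpra_categories()) {
  var_values <- function(recs) {
    if (variable == "pra_category") {
      categories$label[categorize_cpra(recs$initial_cpra, categories)]
    } else {
      if (!variable %in% names(recs)) {
        stop("unknown variable: ", variable)
      }
      recs[[variable]]
    }
  }
  va <- var_values(records)
  vb <- if (!is.null(records_b)) var_values(records_b) else NULL
  levs <- if (variable == "pra_category") {
    categories$label[categories$label %in% unique(c(va, vb))]
  } else sort(unique(c(va, vb)))
  if (length(levs) == 0) {
    warning("empty cohort: no categories observed, percentages reported as 0")
    out <- data.frame(variable = character(0), category = character(0),
                      count_a = integer(0), pct_a = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_a") <- 0L
    attr(out, "n_b") <- if (is.null(vb)) NA_integer_ else length(vb)
    class(out) <- c("msm_categorical_summary", "data.frame")
    return(out)
  }
  count_a <- as.integer(table(factor(va, levels = levs)))
  out <- data.frame(variable = variable, category = levs, count_a = count_a,
                    pct_a = pct_or_zero(count_a), stringsAsFactors = FALSE)
  if (!is.null(vb)) {
    out$count_b <- as.integer(table(factor(vb, levels = levs)))
    out$pct_b <- pct_or_zero(out$count_b)
    out$std_diff <- summary_std_diff(out$count_a, out$count_b)
  }
  attr(out, "n_a") <- length(va)
  attr(out, "n_b") <- if (is.null(vb)) NA_integer_ else length(vb)
  class(out) <- c("msm_categorical_summary", "data.frame")
  out
}

pct_or_zero <- function(counts) {
  n <- sum(counts)
  if (n == 0) {
    warning("empty cohort: percentages undefined, reported as 0")
    return(rep(0, length(counts)))
  }
  100 * counts / n
}

summary_std_diff <- function(count_a, count_b) {
  if (sum(count_a) == 0 || sum(count_b) == 0) return(NA_real_)
  standardized_difference(count_a / sum(count_a), count_b / sum(count_b))
}

#' Build a categorical summary directly from published counts
#'
#' Used to recompute percentages and standardized differences from a printed
#' demographics table (counts per category per cohort).
#'
#' @param variable Variable name.
#' @param category Category labels.
#' @param count_a,count_b Counts per category in each cohort.
#' @return A `msm_categorical_summary` data frame.
#' @export
categorical_summary <- function(variable, category, count_a, count_b = NULL) {
  out <- data.frame(variable = variable, category = category,
                    count_a = as.integer(count_a),
                    pct_a = pct_or_zero(count_a), stringsAsFactors = FALSE)
  if (!is.null(count_b)) {
    out$count_b <- as.integer(count_b)
    out$pct_b <- pct_or_zero(count_b)
    out$std_diff <- summary_std_diff(count_a, count_b)
  }
  attr(out, "n_a") <- sum(count_a)
  attr(out, "n_b") <- if (is.null(count_b)) NA_integer_ else sum(count_b)
  class(out) <- c("msm_categorical_summary", "data.frame")
  out
}

#' @export
print.msm_categorical_summary <- function(x, ...) {
  digits <- if (unique(x$variable)[1] == "pra_category") 2L else 1L
  shown <- x
  shown$pct_a <- round(shown$pct_a, digits)
  if ("pct_b" %in% names(shown)) shown$pct_b <- round(shown$pct_b, digits)
  if ("std_diff" %in% names(shown)) shown$std_diff <- round(shown$std_diff, 4)
  cat("Cohort summary of", unique(x$variable)[1],
      "(n_a =", attr(x, "n_a"),
      if (!is.na(attr(x, "n_b"))) paste(", n_b =", attr(x, "n_b")) else "",
      ")\n")
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Two-cohort demographics report over several variables
#'
#' @param records_a,records_b Registrant records of the two cohorts.
#' @param variables Covariates to summarize.
#' @return Data frame with columns `variable`, `category`, `count_a`,
#'   `pct_a`, `count_b`, `pct_b`, `std_diff`.
#' @export
summarize_cohorts <- function(records_a, records_b,
                              variables = c("age_group", "gender", "abo",
                                            "race", "esrd_diagnosis",
                                            "pra_category")) {
  out <- do.call(rbind, lapply(variables, function(v) {
    s <- summarize(records_a, v, records_b)
    as.data.frame(s)
  }))
  rownames(out) <- NULL
  out
}
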