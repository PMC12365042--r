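#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (pooled within-group variance):
#' F is the ratio of between- to within-group mean squares and p comes
#' from the F distribution.
#'
#' @param samples List of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 observations).
#' @return List with `F`, `p`, `df`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$F  # 3
#' @export
anova_oneway <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 1L) < 2)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  if (is.nan(fit$statistic)) {
    stop("zero within-group variance with equal means: F undefined",
         call. = FALSE)
  }
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two samples.  The U
#' statistic counts, over all pairs, how often an `a` value beats a `b`
#' value (ties count one half).  The p value is exact (null distribution
#' by complete enumeration) when the smaller sample has at most
#' `exact_max` observations and there are no ties; otherwise a
#' tie-corrected normal approximation with continuity correction is
#' used.
#'
#' @param a,b Numeric samples.
#' @param two_sided Two-sided (default) or greater-than alternative.
#' @param exact_max Largest `min(n, m)` for which the exact distribution
#'   is used.
#' @return List with `U`, `p`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # exact 0.1
#' @export
mann_whitney <- function(a, b, two_sided = TRUE, exact_max = 8) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && min(n, m) <= exact_max) {
    lo <- stats::pwilcox(U, n, m)
    hi <- 1 - stats::pwilcox(U - 1, n, m)
    p <- if (two_sided) min(1, 2 * min(lo, hi)) else hi
    method <- "exact"
  } else {
    mu <- n * m / 2
    N <- n + m
    tie_tab <- table(c(a, b))
    corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * (N + 1 - corr))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
    p <- min(1, p)
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' empty.
#'
#' @param p Numeric p values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

# Pull per-observation or per-tank values of one parameter out of a
# rate_series.
param_values <- function(rs, parameter, granularity = c("time", "tank")) {
  granularity <- match.arg(granularity)
  src <- switch(parameter,
                OR = list(rs$hourly, "vo2"), CR = list(rs$hourly, "vco2"),
                RQ = list(rs$hourly, "rq"), AE = list(rs$bihourly, "vn"),
                AQ = list(rs$bihourly, "aq"),
                stop("unknown parameter ", parameter, call. = FALSE))
  df <- src[[1]]
  v <- df[[src[[2]]]]
  if (granularity == "tank") {
    as.numeric(tapply(v, df$tank_id, mean, na.rm = TRUE))
  } else {
    v[!is.na(v)]
  }
}

#' Group summary table with significance annotation
#'
#' Builds the study-style summary grid: per group and parameter the
#' across-tank mean +/- SD, plus two annotation families: stars for the
#' treatment-vs-control contrast and stars for the light-vs-dark
#' contrast within each group.  The headline test is Mann-Whitney;
#' one-way ANOVA p values are reported alongside.
#'
#' `granularity` selects the observations entering the
#' treatment-vs-control test: `"time"` (default) uses the time-resolved
#' records, matching how the study's table reaches p < 0.001; `"tank"`
#' uses tank means, the replication-correct unit (n = 3), on which
#' Mann-Whitney cannot fall below p = 0.1.
#'
#' @param rate_list Named list of `rate_series`, one per group; the
#'   element named `control` (or the first) is the reference.
#' @param granularity `"time"` or `"tank"` for the group contrasts.
#' @return data.frame with one row per group x parameter: `group`,
#'   `parameter`, `mean`, `sd` (across tanks), `p_vs_control`,
#'   `stars_vs_control`, `p_anova`, `p_light_dark`, `stars_light_dark`.
#' @export
summary_table <- function(rate_list, granularity = c("time", "tank")) {
  granularity <- match.arg(granularity)
  stopifnot(is.list(rate_list), length(rate_list) >= 1)
  if (is.null(names(rate_list))) {
    names(rate_list) <- vapply(rate_list, function(r) r$meta$group, "")
  }
  ref <- if ("control" %in% names(rate_list)) "control" else names(rate_list)[1]
  params <- c("OR", "CR", "AE", "RQ", "AQ")
  rows <- list()
  for (gname in names(rate_list)) {
    rs <- rate_list[[gname]]
    gm <- group_means(rs)
    for (p in params) {
      tank_means <- param_values(rs, p, "tank")
      p_ctrl <- p_anova <- NA_real_
      if (gname != ref) {
        x <- param_values(rs, p, granularity)
        y <- param_values(rate_list[[ref]], p, granularity)
        p_ctrl <- mann_whitney(x, y)$p
        p_anova <- anova_oneway(list(x, y))$p
      }
      ph <- phase_test(rs, p)
      rows[[length(rows) + 1]] <- data.frame(
        group = gname, parameter = p,
        mean = gm$mean[gm$parameter == p], sd = gm$sd[gm$parameter == p],
        p_vs_control = p_ctrl, stars_vs_control = significance_stars(p_ctrl),
        p_anova = p_anova,
        p_light_dark = ph$p, stars_light_dark = significance_stars(ph$p))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Light-vs-dark test for one parameter of a dataset
#'
#' Mann-Whitney comparison of photophase vs scotophase time-resolved
#' observations, pooled across tanks.
#'
#' @param rs A `rate_series`.
#' @param parameter One of `OR`, `CR`, `AE`, `RQ`, `AQ`.
#' @return List with `p`, `U`, `light_mean`, `dark_mean`.
#' @export
phase_test <- function(rs, parameter) {
  df <- if (parameter %in% c("AE", "AQ")) rs$bihourly else rs$hourly
  col <- switch(parameter, OR = "vo2", CR = "vco2", RQ = "rq",
                AE = "vn", AQ = "aq")
  ph <- label_phases(df$time_h, rs$meta$schedule, rs$meta$start_clock)
  v <- df[[col]]
  ok <- !is.na(v)
  light <- v[ok & ph == "photophase"]
  dark <- v[ok & ph == "scotophase"]
  mw <- mann_whitney(light, dark)
  list(p = mw$p, U = mw$U, light_mean = mean(light),
       dark_mean = mean(dark))
}

#' Render a summary table as aligned plain text
#'
#' @param tab Output of [summary_table()].
#' @return Character vector of lines (invisibly printed with `cat`).
#' @export
format_summary_table <- function(tab) {
  lines <- character(0)
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, ]
    cells <- sprintf("%s %.2f +/- %.2f%s", sub$parameter, sub$mean,
                     sub$sd, sub$stars_vs_control)
    lines <- c(lines, sprintf("%-10s %s", g, paste(cells, collapse = "  ")))
  }
  lines
}
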