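## Larval zebrafish sleep analysis from 60-s binned activity traces.
## Sleep = a maximal run of >= 1 consecutive bins at or below the
## inactivity threshold (the one-minute-of-inactivity convention);
## endpoints are split by light phase under a lights-on/lights-off
## schedule, with bouts straddling a boundary split at the boundary so
## that sleep + wake exactly partitions each phase.

parse_clock <- function(x) {
  ## "HH:MM" -> minutes since midnight
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("clock time must be 'HH:MM': ", x)
  as.integer(parts[1L]) * 60L + as.integer(parts[2L])
}

#' Construct an activity trace
#'
#' @param activity nonnegative numeric vector, one value per bin.
#' @param larva_id identifier.
#' @param group group label.
#' @param start_clock_time clock time of the first bin, "HH:MM".
#' @param bin_seconds bin width in seconds (default 60).
#' @return an `activity_trace`.
#' @export
activity_trace <- function(activity, larva_id = "larva1", group = "control",
                           start_clock_time = "09:00", bin_seconds = 60L) {
  if (!length(activity)) stop("empty trace")
  if (any(!is.finite(activity)) || any(activity < 0))
    stop("activity must be finite and nonnegative")
  if (bin_seconds <= 0) stop("bin_seconds must be positive")
  structure(list(larva_id = larva_id, group = group,
                 start_clock_time = start_clock_time,
                 bin_seconds = as.integer(bin_seconds),
                 activity = as.numeric(activity)),
            class = "activity_trace")
}

#' Read activity traces from CSV
#'
#' Expected columns: `larva_id`, `group`, `clock_time` ("HH:MM", the
#' first row per larva gives the trace start), `activity`.
#'
#' @param path CSV file.
#' @param bin_seconds bin width (default 60).
#' @return named list of `activity_trace` objects.
#' @export
read_activity_traces <- function(path, bin_seconds = 60L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "group", "clock_time", "activity")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  traces <- lapply(split(df, df$larva_id), function(d)
    activity_trace(d$activity, larva_id = d$larva_id[1L],
                   group = d$group[1L],
                   start_clock_time = d$clock_time[1L],
                   bin_seconds = bin_seconds))
  traces[unique(df$larva_id)]
}

#' Detect sleep and wake bouts
#'
#' A sleep bout is a maximal run of consecutive bins with activity at or
#' below `inactivity_threshold`; wake bouts are the complementary runs.
#'
#' @param trace an `activity_trace`.
#' @param inactivity_threshold nonnegative activity cutoff (default 0).
#' @return list of data frames `sleep` and `wake`, each with `start_bin`
#'   and `length_bins`.
#' @export
detect_sleep_bouts <- function(trace, inactivity_threshold = 0) {
  stopifnot(inherits(trace, "activity_trace"))
  if (inactivity_threshold < 0) stop("threshold must be nonnegative")
  asleep <- trace$activity <= inactivity_threshold
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mk <- function(sel) data.frame(start_bin = starts[sel],
                                 length_bins = r$lengths[sel])
  list(sleep = mk(r$values), wake = mk(!r$values))
}

## phase ("day"/"night") of each bin by clock time
bin_phases <- function(trace, lights_on = "09:00", lights_off = "23:00") {
  on <- parse_clock(lights_on); off <- parse_clock(lights_off)
  start <- parse_clock(trace$start_clock_time)
  nb <- length(trace$activity)
  minute <- (start + (seq_len(nb) - 1L) * trace$bin_seconds / 60) %% 1440
  if (on < off) ifelse(minute >= on & minute < off, "day", "night")
  else ifelse(minute >= on | minute < off, "day", "night")
}

#' Summarize sleep architecture by light phase
#'
#' Bins are assigned to day or night by clock time; bouts spanning a
#' lights-on/off boundary are split at the boundary and each fragment
#' counts as a bout in its phase, which keeps sleep + wake equal to the
#' phase duration exactly. A `total` row summarizes the whole trace with
#' unsplit bouts.
#'
#' @param trace an `activity_trace`.
#' @param lights_on,lights_off schedule clock times (defaults 09:00 /
#'   23:00, the 14 h / 10 h light-dark cycle).
#' @param inactivity_threshold passed to [detect_sleep_bouts()].
#' @return a `sleep_summary` data frame with rows day/night/total and
#'   columns: phase, phase_minutes, total_sleep_minutes,
#'   sleep_bout_count, mean_sleep_bout_length_minutes, wake_bout_count,
#'   mean_wake_bout_length_minutes, larva_id, group.
#' @export
phase_summary <- function(trace, lights_on = "09:00", lights_off = "23:00",
                          inactivity_threshold = 0) {
  phases <- bin_phases(trace, lights_on, lights_off)
  asleep <- trace$activity <= inactivity_threshold
  binmin <- trace$bin_seconds / 60
  ## runs of constant (phase, state): fragments split at phase boundaries
  key <- paste(phases, asleep)
  r <- rle(key)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  frag <- data.frame(phase = phases[starts], asleep = asleep[starts],
                     length = r$lengths)
  whole <- detect_sleep_bouts(trace, inactivity_threshold)
  one <- function(ph) {
    if (ph == "total") {
      sl <- whole$sleep$length_bins; wk <- whole$wake$length_bins
      pm <- length(trace$activity) * binmin
    } else {
      sl <- frag$length[frag$phase == ph & frag$asleep]
      wk <- frag$length[frag$phase == ph & !frag$asleep]
      pm <- sum(phases == ph) * binmin
    }
    data.frame(phase = ph, phase_minutes = pm,
               total_sleep_minutes = sum(sl) * binmin,
               sleep_bout_count = length(sl),
               mean_sleep_bout_length_minutes =
                 if (length(sl)) mean(sl) * binmin else 0,
               wake_bout_count = length(wk),
               mean_wake_bout_length_minutes =
                 if (length(wk)) mean(wk) * binmin else 0,
               larva_id = trace$larva_id, group = trace$group,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("day"), one("night"), one("total"))
  class(out) <- c("sleep_summary", class(out))
  out
}

#' Per-larva endpoint table for a set of traces
#' @param traces list of `activity_trace` objects.
#' @param ... passed to [phase_summary()].
#' @return data frame of all per-larva, per-phase summaries.
#' @export
summarize_traces <- function(traces, ...) {
  do.call(rbind, lapply(traces, phase_summary, ...))
}

## D'Agostino & Pearson omnibus normality test (K^2 = Z1^2 + Z2^2 against
## chi-square with 2 df), using D'Agostino's skewness transformation and
## the Anscombe-Glynn kurtosis transformation. Requires n >= 8.
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 8L) return(list(statistic = NA_real_, p_value = NA_real_, n = n))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  ## skewness
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  ## kurtosis
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  list(statistic = K2,
       p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE), n = n)
}

## step-down Holm-Sidak adjustment of pairwise p-values
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    val <- 1 - (1 - p[o[k]])^(m - k + 1)
    running <- max(running, val)
    adj[o[k]] <- min(1, running)
  }
  adj
}

## single-step Sidak adjustment (Dunn-Sidak)
sidak_adjust <- function(p) {
  pmin(1, 1 - (1 - p)^length(p))
}

stars_for_p <- function(p) {
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

## Dunn's pairwise z tests on pooled ranks (post hoc to Kruskal-Wallis)
dunn_pairwise <- function(values, groups) {
  rk <- rank(values)
  n <- length(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  gl <- unique(groups)
  res <- list()
  for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
    a <- gl[i]; b <- gl[j]
    na <- sum(groups == a); nb <- sum(groups == b)
    z <- (mean(rk[groups == a]) - mean(rk[groups == b])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    res[[length(res) + 1L]] <- data.frame(
      group1 = a, group2 = b, statistic = z,
      p_raw = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Normality-gated group comparison of a sleep endpoint
#'
#' The gate follows the standard behavioral-statistics recipe: every
#' group must pass both the D'Agostino & Pearson omnibus test and the
#' Shapiro-Wilk test at alpha = 0.05 for the parametric branch (one-way
#' ANOVA with Holm-Sidak pairwise comparisons); otherwise
#' Kruskal-Wallis with Dunn-Sidak pairwise comparisons is used. A
#' zero-variance group forces the nonparametric branch with a warning.
#' For groups too small for the omnibus test (n < 8) the gate relies on
#' Shapiro-Wilk alone.
#'
#' @param summaries a [summarize_traces()] data frame (or any data frame
#'   with `group` and the endpoint column).
#' @param endpoint column name to compare, e.g. `"total_sleep_minutes"`.
#' @param phase which phase rows to use (default `"day"`); ignored when
#'   the table has no `phase` column.
#' @param alpha normality-gate level (default 0.05).
#' @return a `group_comparison` list: branch taken, omnibus statistic and
#'   p, pairwise table with adjusted p and significance stars, normality
#'   table.
#' @export
compare_groups <- function(summaries, endpoint, phase = "day",
                           alpha = 0.05) {
  df <- as.data.frame(summaries)
  if ("phase" %in% names(df)) df <- df[df$phase == phase, , drop = FALSE]
  if (!endpoint %in% names(df)) stop("unknown endpoint: ", endpoint)
  values <- df[[endpoint]]
  groups <- as.character(df$group)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 3L)) stop("each group needs at least 3 larvae")
  norm <- do.call(rbind, lapply(names(sizes), function(g) {
    x <- values[groups == g]
    sw <- if (stats::var(x) > 0) stats::shapiro.test(x)$p.value else NA_real_
    dp <- if (stats::var(x) > 0) dagostino_pearson_test(x)$p_value else NA_real_
    data.frame(group = g, n = length(x), shapiro_p = sw,
               dagostino_p = dp, zero_variance = stats::var(x) == 0,
               stringsAsFactors = FALSE)
  }))
  degenerate <- any(norm$zero_variance)
  if (degenerate)
    warning("zero-variance group; using the nonparametric branch")
  pass <- !degenerate &&
    all(norm$shapiro_p > alpha, na.rm = FALSE) &&
    all(is.na(norm$dagostino_p) | norm$dagostino_p > alpha)
  pass <- isTRUE(pass)
  if (pass) {
    fit <- stats::aov(values ~ factor(groups))
    an <- summary(fit)[[1L]]
    statistic <- an[["F value"]][1L]
    p <- an[["Pr(>F)"]][1L]
    gl <- names(sizes)
    pw <- list()
    for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
      tt <- stats::t.test(values[groups == gl[i]], values[groups == gl[j]],
                          var.equal = TRUE)
      pw[[length(pw) + 1L]] <- data.frame(
        group1 = gl[i], group2 = gl[j],
        statistic = unname(tt$statistic), p_raw = tt$p.value,
        stringsAsFactors = FALSE)
    }
    pw <- do.call(rbind, pw)
    pw$p_adj <- holm_sidak_adjust(pw$p_raw)
    branch <- "anova_holm_sidak"
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
    statistic <- unname(kw$statistic)
    p <- kw$p.value
    pw <- dunn_pairwise(values, groups)
    pw$p_adj <- sidak_adjust(pw$p_raw)
    branch <- "kruskal_dunn_sidak"
  }
  pw$stars <- stars_for_p(pw$p_adj)
  structure(list(branch = branch, endpoint = endpoint, phase = phase,
                 statistic = statistic, p_value = p,
                 pairwise = pw, normality = norm,
                 degenerate_group = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s phase): %s, p = %.4g\n",
              x$endpoint, x$phase, x$branch, x$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
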