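#' Build a longitudinal activity table from per-session summaries
#'
#' Stacks per-neuron per-session activity summaries into the tidy long-format
#' table all cross-session statistics consume. Every neuron must be present
#' in every session it is analysed for.
#'
#' @param summaries data.frame with columns `neuron_id`, `session`
#'   (or `session_id`), `transients_per_min` (or `rate`), optionally
#'   `auc_per_min`, `category`, `fov_id`, `cohort`.
#' @return a `longitudinal_table` (data.frame with columns `neuron_id`,
#'   `session`, `rate`, `auc`, `category`, `fov_id`, `cohort`).
#' @export
longitudinal_table <- function(summaries) {
  x <- as.data.frame(summaries)
  if (!"session" %in% names(x) && "session_id" %in% names(x))
    x$session <- x$session_id
  if (!"rate" %in% names(x) && "transients_per_min" %in% names(x))
    x$rate <- x$transients_per_min
  stopifnot(all(c("neuron_id", "session", "rate") %in% names(x)))
  if (any(x$rate < 0, na.rm = TRUE)) stop("rates must be >= 0", call. = FALSE)
  if (anyDuplicated(x[c("neuron_id", "session")]))
    stop("duplicate neuron/session rows", call. = FALSE)
  out <- data.frame(
    neuron_id = x$neuron_id, session = x$session, rate = x$rate,
    auc = x$auc_per_min %||% x$auc %||% rep(NA_real_, nrow(x)),
    category = if ("category" %in% names(x))
      factor(x$category, levels = c("rare", "intermediate", "high"))
    else classify_activity(x$rate),
    fov_id = x$fov_id %||% rep(1L, nrow(x)),
    cohort = x$cohort %||% rep(NA_character_, nrow(x)))
  class(out) <- c("longitudinal_table", "data.frame")
  out
}

# neurons present at both sessions, rates aligned; preserves neuron order of s0
match_sessions <- function(table, s0, s1) {
  a <- table[table$session == s0, ]
  b <- table[table$session == s1, ]
  ids <- a$neuron_id[a$neuron_id %in% b$neuron_id]
  if (length(ids) == 0L) stop("no matched neurons between sessions", call. = FALSE)
  a <- a[match(ids, a$neuron_id), ]
  b <- b[match(ids, b$neuron_id), ]
  list(ids = ids, a = a, b = b)
}

#' Per-neuron change in activity between two sessions
#'
#' @param table a [longitudinal_table()].
#' @param s0,s1 session identifiers (change is `s1 - s0`).
#' @return data.frame `neuron_id`, `fov_id`, `delta_rate` (transients/min),
#'   in the neuron order of session `s0`.
#' @export
activity_change <- function(table, s0, s1) {
  m <- match_sessions(table, s0, s1)
  data.frame(neuron_id = m$ids, fov_id = m$a$fov_id,
             delta_rate = m$b$rate - m$a$rate)
}

#' Similarity index of activity between two sessions
#'
#' Pearson correlation, across neurons of one field of view, of per-neuron
#' transient rates at two sessions. High values mean neurons keep their
#' relative activity levels; shuffling neuron identity drives it to zero.
#'
#' @param rates_s0,rates_s1 per-neuron rate vectors (same neurons, same
#'   order).
#' @return correlation in `[-1, 1]`, or `NA` (with a warning) when fewer
#'   than 3 neurons or either vector is constant.
#' @export
similarity_index <- function(rates_s0, rates_s1) {
  stopifnot(length(rates_s0) == length(rates_s1))
  if (length(rates_s0) < 3L) {
    warning("similarity index needs >= 3 neurons", call. = FALSE)
    return(NA_real_)
  }
  if (sd(rates_s0) == 0 || sd(rates_s1) == 0) {
    warning("similarity index undefined for constant rate vector",
            call. = FALSE)
    return(NA_real_)
  }
  cor(rates_s0, rates_s1)
}

#' Shuffle null distribution of the similarity index
#'
#' Permutes neuron identity at the later session and recomputes the
#' similarity index, per field of view; the per-shuffle statistic is the mean
#' over FOVs with a defined index.
#'
#' @param table a [longitudinal_table()].
#' @param s0,s1 sessions.
#' @param n_shuffles number of random permutations.
#' @param seed integer seed.
#' @param exhaustive if TRUE and the (single-FOV) table has at most 7
#'   neurons, enumerate all permutations instead of sampling.
#' @return numeric vector of null similarity values; attribute `observed`
#'   holds the unshuffled mean similarity.
#' @export
shuffle_null_similarity <- function(table, s0, s1, n_shuffles = 100, seed = 1,
                                    exhaustive = FALSE) {
  stopifnot(n_shuffles >= 1)
  m <- match_sessions(table, s0, s1)
  fovs <- split(seq_along(m$ids), m$a$fov_id)
  si_fov <- function(perm_within) {
    vals <- vapply(fovs, function(idx) {
      y <- m$b$rate[idx]
      if (perm_within) y <- y[sample.int(length(y))]
      suppressWarnings(similarity_index(m$a$rate[idx], y))
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  observed <- si_fov(FALSE)
  set.seed(as.integer(seed))
  if (exhaustive) {
    if (length(fovs) != 1L || length(m$ids) > 7L)
      stop("exhaustive mode requires a single FOV with <= 7 neurons",
           call. = FALSE)
    perms <- all_permutations(length(m$ids))
    out <- apply(perms, 1, function(p)
      suppressWarnings(similarity_index(m$a$rate, m$b$rate[p])))
  } else {
    out <- vapply(seq_len(n_shuffles), function(k) si_fov(TRUE), numeric(1))
  }
  attr(out, "observed") <- observed
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Category transition matrix between two sessions
#'
#' @param table a [longitudinal_table()].
#' @param s0,s1 sessions.
#' @return list with `counts` (3x3, rows = category at `s0`, columns = at
#'   `s1`, order rare/intermediate/high), `fractions` (row-normalised; rows
#'   with no neurons are `NaN`), `recruitment_rate` (fraction
#'   intermediate -> high) and `n` (matched neurons).
#' @export
transition_matrix <- function(table, s0, s1) {
  m <- match_sessions(table, s0, s1)
  lv <- c("rare", "intermediate", "high")
  counts <- base::table(factor(m$a$category, levels = lv),
                        factor(m$b$category, levels = lv))
  counts <- unclass(as.matrix(counts))
  fractions <- counts / rowSums(counts)
  list(counts = counts, fractions = fractions,
       recruitment_rate = fractions["intermediate", "high"],
       n = length(m$ids))
}

#' Reoccurrence rate of an activity category
#'
#' Fraction of the neurons in `category` at `s0` that are still in the same
#' category at `s1`, pooled over neurons and per field of view.
#'
#' @param table a [longitudinal_table()].
#' @param category `"rare"`, `"intermediate"` or `"high"`.
#' @param s0,s1 sessions.
#' @return list with `pooled` (fraction over all eligible neurons), `by_fov`
#'   (named vector; FOVs with no neuron in `category` at `s0` are excluded)
#'   and `n` (eligible neurons).
#' @export
reoccurrence_rate <- function(table, category, s0, s1) {
  category <- match.arg(category, c("rare", "intermediate", "high"))
  m <- match_sessions(table, s0, s1)
  sel <- m$a$category == category
  if (!any(sel)) stop("no neuron in category at s0", call. = FALSE)
  same <- m$b$category[sel] == category
  fov <- m$a$fov_id[sel]
  by_fov <- tapply(same, fov, mean)
  list(pooled = mean(same), by_fov = by_fov, n = sum(sel))
}

#' Recruitment of novel highly active neurons
#'
#' Identifies neurons that are highly active at `s_new` but were not at
#' `s_prev`, reports which category they came from, and the mean activity
#' gain with a seeded percentile-bootstrap confidence interval.
#'
#' @param table a [longitudinal_table()].
#' @param s_prev,s_new sessions (novelty is relative to `s_prev`).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list with `n_novel`, `source_fractions` (named, over
#'   rare/intermediate at `s_prev`; `NA` and flagged when no novel cell),
#'   `mean_gain`, `gain_ci`, `neuron_ids`.
#' @export
novel_high_analysis <- function(table, s_prev, s_new, n_boot = 10000,
                                seed = 1, conf = 0.95) {
  m <- match_sessions(table, s_prev, s_new)
  novel <- m$b$category == "high" & m$a$category != "high"
  if (!any(novel)) {
    return(list(n_novel = 0L,
                source_fractions = c(rare = NA_real_, intermediate = NA_real_),
                mean_gain = NA_real_, gain_ci = c(NA_real_, NA_real_),
                neuron_ids = integer(0), empty = TRUE))
  }
  src <- factor(m$a$category[novel], levels = c("rare", "intermediate"))
  gain <- m$b$rate[novel] - m$a$rate[novel]
  set.seed(as.integer(seed))
  boots <- vapply(seq_len(n_boot), function(k)
    mean(gain[sample.int(length(gain), replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  list(n_novel = sum(novel),
       source_fractions = prop.table(base::table(src)),
       mean_gain = mean(gain),
       gain_ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       neuron_ids = m$ids[novel], empty = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison of activity-change distributions
#'
#' `D` is the supremum distance between the two empirical CDFs, computed by a
#' direct scan over the pooled sample points. The p-value is exact
#' (conditional on ties) for `n * m <= 10000` and uses the asymptotic
#' Kolmogorov series otherwise.
#'
#' @param deltas_a,deltas_b numeric samples (e.g. per-neuron rate changes).
#' @return list with `D`, `p_value`, `n`, `m`, `exact`.
#' @export
compare_change_distributions <- function(deltas_a, deltas_b) {
  a <- as.numeric(deltas_a); b <- as.numeric(deltas_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(a); m <- length(b)
  pts <- sort(unique(c(a, b)))
  ecdf_a <- vapply(pts, function(x) mean(a <= x), numeric(1))
  ecdf_b <- vapply(pts, function(x) mean(b <= x), numeric(1))
  d <- max(abs(ecdf_a - ecdf_b))
  exact <- (as.double(n) * m) <= 10000
  p <- if (exact) {
    stats::psmirnov(d, sizes = c(n, m), z = c(a, b), two.sided = TRUE,
                    exact = TRUE, lower.tail = FALSE)
  } else {
    t_stat <- sqrt(n * m / (n + m)) * d
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t_stat^2))))
  }
  list(D = d, p_value = p, n = n, m = m, exact = exact)
}

#' Mann-Whitney U comparison
#'
#' Rank-sum statistic `U` for the first sample. The p-value is exact (via
#' the null U distribution) when there are no ties and `n * m <= 10000`, and
#' uses the tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `U`, `p_value`, `n`, `m`, `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  exact <- !has_ties && (as.double(n) * m) <= 10000
  if (exact) {
    p <- if (u > n * m / 2)
      2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    else
      2 * stats::pwilcox(u, n, m)
    p <- min(1, p)
  } else {
    mu <- n * m / 2
    sigma2 <- (n * m / 12) * ((n + m + 1) -
                                sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- u - mu
    z <- z - sign(z) * 0.5  # continuity correction
    z <- z / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(U = u, p_value = p, n = n, m = m, exact = exact)
}
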