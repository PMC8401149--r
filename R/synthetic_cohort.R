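# Synthetic cohort generation.
#
# Design: each feature's marginal is a truncated normal (or, for the two
# long-tailed step-count features, a log-normal) whose underlying parameters
# are numerically moment-matched so that the *truncated* distribution has
# exactly the requested mean/SD. Sampling goes through a Gaussian copula: a
# latent standard-normal vector per participant, an exchangeable correlation
# among the non-posture features, and a zero-weighted-sum correlation block
# for the four posture percentages so that their sum concentrates at 100.
# Phenotype coupling is a quantile map between flag-off and flag-on branch
# distributions whose branch moments are chosen to preserve the FG marginal
# mean and variance exactly.

# ---- truncated-normal moment matching ------------------------------------

trunc_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (!is.finite(Z) || Z < 1e-12) return(c(NA_real_, NA_real_))
  pa <- if (is.finite(a)) stats::dnorm(a) else 0
  pb <- if (is.finite(b)) stats::dnorm(b) else 0
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mu + sigma * (pa - pb) / Z
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(m, sqrt(max(v, 0)))
}

.match_cache <- new.env(parent = emptyenv())

# Find underlying (mu, sigma) such that the [lo, hi]-truncated normal has the
# target mean m and sd s. Cached; near-identity when truncation is negligible.
match_truncnorm <- function(m, s, lo, hi) {
  key <- paste(signif(c(m, s, lo, hi), 12), collapse = "|")
  hit <- .match_cache[[key]]
  if (!is.null(hit)) return(hit)
  # truncation negligible: bounds beyond ~8 sd of the mean
  if ((!is.finite(lo) || lo < m - 8 * s) && (!is.finite(hi) || hi > m + 8 * s)) {
    out <- c(mu = m, sigma = s)
    .match_cache[[key]] <- out
    return(out)
  }
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    mom <- trunc_moments(mu, sigma, lo, hi)
    if (anyNA(mom)) return(1e10)
    ((mom[1] - m) / s)^2 + ((mom[2] - s) / s)^2
  }
  fit <- stats::optim(c(m, log(s)), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  if (fit$value > 1e-6) {
    # retry from a spread-out start before giving up
    fit2 <- stats::optim(c(m - s, log(2 * s)), obj,
                         control = list(reltol = 1e-14, maxit = 5000))
    if (fit2$value < fit$value) fit <- fit2
  }
  if (fit$value > 1e-4) {
    warnf("truncated-normal moment match imprecise for mean=%g sd=%g", m, s)
  }
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  .match_cache[[key]] <- out
  out
}

# ---- branch (marginal) distributions -------------------------------------

# A branch describes one marginal: quantile and CDF closures over [lo, hi].
branch_truncnorm <- function(m, s, lo, hi) {
  par <- match_truncnorm(m, s, lo, hi)
  mu <- par[["mu"]]; sigma <- par[["sigma"]]
  pa <- stats::pnorm((lo - mu) / sigma)
  pb <- stats::pnorm((hi - mu) / sigma)
  Z <- pb - pa
  list(
    q = function(u) {
      x <- mu + sigma * stats::qnorm(pa + u * Z)
      pmin(pmax(x, lo), hi)
    },
    p = function(x) {
      u <- (stats::pnorm((x - mu) / sigma) - pa) / Z
      pmin(pmax(u, 0), 1)
    }
  )
}

branch_lognormal <- function(m, s) {
  stopifnot(m > 0)
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  list(
    q = function(u) stats::qlnorm(pmin(pmax(u, 1e-15), 1 - 1e-15),
                                  meanlog, sdlog),
    p = function(x) stats::plnorm(pmax(x, 0), meanlog, sdlog)
  )
}

make_branch <- function(m, s, support, distribution) {
  lo <- 0
  hi <- if (support == "percentage") 100 else Inf
  if (distribution == "lognormal") branch_lognormal(m, s)
  else branch_truncnorm(m, s, lo, hi)
}

# ---- phenotype coupling: branch moments ----------------------------------

# For an FG feature in a coupled phenotype class, split the group marginal
# (fg_mean, fg_sd) into one branch per coupling-intensity level I so that
#   sum_I p_I * m_I = fg_mean  and  sum_I p_I * s_I^2 + Var_I(m_I) = fg_sd^2.
# `levels` is a data.frame with columns I (intensity in [0, 1]) and prob.
# Additive split for truncated-normal features; multiplicative (ratio toward
# the RG/FG mean ratio) for log-normal features so means stay positive.
coupling_branches <- function(fs, levels, coupling) {
  m <- fs$fg_mean; s <- fs$fg_sd
  delta <- fs$fg_mean - fs$rg_mean
  Ibar <- sum(levels$prob * levels$I)
  varI <- sum(levels$prob * (levels$I - Ibar)^2)
  if (coupling == 0 || varI == 0 || delta == 0) {
    return(data.frame(I = levels$I, m = m, s = s))
  }
  if (fs$distribution == "lognormal") {
    r <- (fs$fg_mean / fs$rg_mean)^coupling
    w <- r^(levels$I - Ibar)
    k <- sum(levels$prob * w)
    m_I <- m * w / k
    resid <- s^2 - sum(levels$prob * (m_I - m)^2)
    resid <- max(resid, (0.3 * s)^2)
    cv <- sqrt(resid / sum(levels$prob * m_I^2))
    return(data.frame(I = levels$I, m = m_I, s = cv * m_I))
  }
  m_I <- m + coupling * delta * (levels$I - Ibar)
  s_resid <- sqrt(max(s^2 - (coupling * delta)^2 * varI, (0.3 * s)^2))
  if (any(m_I <= 0)) {
    warnf("coupling drives '%s' branch mean non-positive; clamping", fs$name)
    m_I <- pmax(m_I, 1e-6)
  }
  data.frame(I = levels$I, m = m_I, s = s_resid)
}

# ---- phenotype flag calibration ------------------------------------------

# Underlying independent Bernoulli rates such that, conditional on at least
# one flag being set (the Fried rule for FG membership), each flag's marginal
# prevalence equals the target. Fixed-point iteration on
#   p_i = target_i * (1 - prod(1 - p_j)).
calibrate_flag_rates <- function(target) {
  target <- pmin(pmax(target, 0), 1)
  if (all(target == 0)) return(target)
  p <- target
  for (it in seq_len(200L)) {
    q <- prod(1 - p)
    p_new <- pmin(target * (1 - q), 1)
    if (max(abs(p_new - p)) < 1e-12) break
    p <- p_new
  }
  p
}

# Per-class coupling-intensity distributions within FG, computed exactly by
# enumerating the 2^5 flag combinations under the calibrated independent
# rates, conditional on at least one flag (the Fried FG rule). Slowness and
# weakness share their feature class, so that class's intensity is the mean
# of the two flags (0, 0.5, 1); exhaustion and inactivity are binary.
class_intensity <- function(flags) {
  list(slowness_weakness = (flags[, "slowness"] + flags[, "weakness"]) / 2,
       exhaustion = flags[, "exhaustion"],
       inactivity = flags[, "inactivity"])
}

class_levels <- function(rates) {
  combos <- as.matrix(expand.grid(rep(list(0:1), length(rates))))
  colnames(combos) <- names(rates)
  pr <- apply(combos, 1L, function(f) prod(rates^f * (1 - rates)^(1 - f)))
  keep <- rowSums(combos) >= 1L
  combos <- combos[keep, , drop = FALSE]
  pr <- pr[keep] / sum(pr[keep])
  ints <- class_intensity(combos)
  lapply(ints, function(I) {
    agg <- tapply(pr, I, sum)
    data.frame(I = as.numeric(names(agg)), prob = as.numeric(agg))
  })
}

# ---- posture correlation block -------------------------------------------

# Correlation matrix for the four posture latents with weighted column sum
# zero: unit vectors v_i in the plane closing a polygon with side lengths w_i
# (the marginal SDs), so sum_i w_i z_i = 0 on the latent scale and the
# posture percentages co-vary negatively, keeping their sum near 100.
posture_loadings <- function(w) {
  stopifnot(length(w) == 4L, all(w > 0))
  if (max(w) > sum(w) - max(w)) {
    # polygon cannot close; caller falls back to independent latents
    return(NULL)
  }
  lo <- max(abs(w[1] - w[2]), abs(w[3] - w[4]))
  hi <- min(w[1] + w[2], w[3] + w[4])
  r <- (lo + hi) / 2
  pair_vecs <- function(a, b, r, sign) {
    # two unit vectors with lengths a,b whose weighted sum is (sign*r, 0)
    ca <- (a^2 + r^2 - b^2) / (2 * a * r)
    ca <- min(max(ca, -1), 1)
    sa <- sqrt(1 - ca^2)
    va <- c(ca, sa)
    vb <- c((r - a * ca) / b, -a * sa / b)
    rbind(va, vb) * c(sign, sign)
  }
  V <- rbind(pair_vecs(w[1], w[2], r, 1), pair_vecs(w[3], w[4], r, -1))
  # rows are unit up to fp error; renormalize
  V / sqrt(rowSums(V^2))
}

# ---- flag and demographic sampling ---------------------------------------

draw_fg_flags <- function(n, rates) {
  k <- length(rates)
  flags <- matrix(stats::rbinom(n * k, 1L, rep(rates, each = n)), nrow = n)
  # Fried rule: FG members have >= 1 phenotype; redraw all-zero rows so the
  # accepted distribution is the conditional one the calibration targets.
  bad <- which(rowSums(flags) == 0L)
  guard <- 0L
  while (length(bad) > 0L && guard < 10000L) {
    flags[bad, ] <- matrix(stats::rbinom(length(bad) * k, 1L,
                                         rep(rates, each = length(bad))),
                           nrow = length(bad))
    bad <- bad[rowSums(flags[bad, , drop = FALSE]) == 0L]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) flags[bad, sample.int(k, length(bad), replace = TRUE)] <- 1L
  colnames(flags) <- names(rates)
  flags
}

draw_demographics <- function(n, par) {
  age <- branch_truncnorm(par$age[1], par$age[2], 65, Inf)$q(stats::runif(n))
  height <- branch_truncnorm(par$height[1], par$height[2], 120, 210)$q(stats::runif(n))
  bmi <- branch_truncnorm(par$bmi[1], par$bmi[2], 12, 70)$q(stats::runif(n))
  gender <- if (n == 0L) character(0) else
    ifelse(stats::runif(n) < par$p_female, "female", "male")
  weight <- bmi * (height / 100)^2
  data.frame(age = age, gender = gender, height_cm = height,
             weight_kg = weight, bmi = bmi, stringsAsFactors = FALSE)
}

# ---- feature matrix for one group ----------------------------------------

# flags: n x 5 integer matrix (all zero for RG). group: "rg" or "fg".
draw_features <- function(n, spec, group, flags) {
  fspecs <- spec$feature_specs
  k <- nrow(fspecs)
  if (n == 0L) {
    return(matrix(numeric(0), 0L, k, dimnames = list(NULL, fspecs$name)))
  }
  post <- match(posture_features(), fspecs$name)
  post <- post[!is.na(post)]
  nonpost <- setdiff(seq_len(k), post)
  rho <- spec$within_group_correlation

  # latent standard normals: exchangeable factor for non-posture features,
  # planar zero-weighted-sum block for the posture composition
  z <- matrix(NA_real_, n, k)
  if (length(nonpost) > 0L) {
    g <- stats::rnorm(n)
    e <- matrix(stats::rnorm(n * length(nonpost)), n, length(nonpost))
    z[, nonpost] <- sqrt(rho) * g + sqrt(1 - rho) * e
  }
  if (length(post) == 4L) {
    w <- if (group == "rg") fspecs$rg_sd[post] else fspecs$fg_sd[post]
    V <- posture_loadings(w)
    e2 <- matrix(stats::rnorm(n * 2L), n, 2L)
    if (is.null(V)) {
      z[, post] <- matrix(stats::rnorm(n * 4L), n, 4L)
    } else {
      z[, post] <- e2 %*% t(V)
    }
  } else if (length(post) > 0L) {
    z[, post] <- matrix(stats::rnorm(n * length(post)), n, length(post))
  }

  rates <- calibrate_flag_rates(spec$phenotype_prevalence)
  levels <- if (group == "fg") class_levels(rates) else NULL
  row_int <- if (group == "fg") class_intensity(flags) else NULL

  x <- matrix(NA_real_, n, k, dimnames = list(NULL, fspecs$name))
  for (j in seq_len(k)) {
    fs <- as.list(fspecs[j, ])
    u <- stats::pnorm(z[, j])
    if (group == "rg") {
      br <- make_branch(fs$rg_mean, fs$rg_sd, fs$support, fs$distribution)
      x[, j] <- br$q(u)
    } else {
      cls <- fs$phenotype_class
      if (!cls %in% names(levels) || spec$coupling == 0) {
        br <- make_branch(fs$fg_mean, fs$fg_sd, fs$support, fs$distribution)
        x[, j] <- br$q(u)
      } else {
        bm <- coupling_branches(fs, levels[[cls]], spec$coupling)
        Irow <- row_int[[cls]]
        xi <- numeric(n)
        for (r in seq_len(nrow(bm))) {
          sel <- Irow == bm$I[r]
          if (any(sel)) {
            br <- make_branch(bm$m[r], bm$s[r], fs$support, fs$distribution)
            xi[sel] <- br$q(u[sel])
          }
        }
        x[, j] <- xi
      }
    }
  }

  # compositional projection: the four posture states exhaust the 24-h day
  # (their spec means sum to exactly 100 in both groups), so each row's
  # posture block is renormalized onto the sum-100 simplex. The zero-sum
  # latent structure keeps the factor within a fraction of a percent.
  if (length(post) == 4L) {
    s <- rowSums(x[, post, drop = FALSE])
    ok <- is.finite(s) & s > 0
    x[ok, post] <- x[ok, post, drop = FALSE] * (100 / s[ok])
  }
  x
}

#' Apply phenotype coupling to already-drawn participant features
#'
#' Quantile-maps the features of each coupled phenotype class from the
#' flag-off branch distribution to the flag-on branch distribution for rows
#' whose class flag is set. Rows with all flags off (in particular every
#' robust participant) are returned unchanged, and a coupling strength of 0
#' makes the map the identity. This is the participant-level view of the
#' coupling the generator applies at draw time; [generate_cohort()] already
#' includes it.
#'
#' @param spec A [cohort_spec()].
#' @param cohort A cohort data frame (see [generate_cohort()]) whose frail
#'   rows were drawn from the plain (coupling-free) FG marginals.
#' @param coupling Optional override of `spec$coupling`.
#' @return The cohort with coupled feature columns quantile-mapped to the
#'   intensity branch implied by each frail row's phenotype flags.
#' @export
phenotype_coupling <- function(spec, cohort, coupling = spec$coupling) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (coupling == 0) return(cohort)
  fspecs <- spec$feature_specs
  rates <- calibrate_flag_rates(spec$phenotype_prevalence)
  levels <- class_levels(rates)
  fg <- which(cohort$frailty_status == 1L)
  if (length(fg) == 0L) return(cohort)
  flags <- as.matrix(cohort[fg, phenotype_names(), drop = FALSE])
  row_int <- class_intensity(flags)
  for (j in seq_len(nrow(fspecs))) {
    fs <- as.list(fspecs[j, ])
    cls <- fs$phenotype_class
    if (!cls %in% names(levels)) next
    bm <- coupling_branches(fs, levels[[cls]], coupling)
    b_marg <- make_branch(fs$fg_mean, fs$fg_sd, fs$support, fs$distribution)
    Irow <- row_int[[cls]]
    for (r in seq_len(nrow(bm))) {
      sel <- fg[Irow == bm$I[r]]
      if (length(sel) > 0L) {
        br <- make_branch(bm$m[r], bm$s[r], fs$support, fs$distribution)
        cohort[[fs$name]][sel] <- br$q(b_marg$p(cohort[[fs$name]][sel]))
      }
    }
  }
  post <- intersect(posture_features(), fspecs$name)
  if (length(post) == 4L) {
    s <- rowSums(cohort[, post])
    ok <- which(is.finite(s) & s > 0)
    cohort[ok, post] <- cohort[ok, post] * (100 / s[ok])
  }
  cohort
}

#' Generate a synthetic frailty cohort
#'
#' Draws a participant table with the statistical structure the downstream
#' analysis assumes: robust participants (RG) with zero Fried phenotype
#' flags; pre-frail/frail participants (FG) with at least one flag, flag
#' prevalences calibrated to the spec; feature values drawn from per-group
#' moment-matched marginals with a Gaussian-copula dependence structure; and
#' the four posture percentages kept on the simplex (each in [0, 100], sum
#' at most 100). Deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()]; see [default_cohort_spec()].
#' @return A data.frame of class `frail_cohort` with columns `id`, `age`,
#'   `gender`, `height_cm`, `weight_kg`, `bmi`, `frailty_status` (0 = robust,
#'   1 = pre-frail/frail), the five phenotype flags, and the twelve feature
#'   columns of [feature_table()].
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 7))
#' table(cohort$frailty_status)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  n_rg <- spec$n_robust
  n_fg <- spec$n_frail
  pn <- phenotype_names()
  with_seed(spec$seed, {
    rates <- calibrate_flag_rates(spec$phenotype_prevalence)
    flags_fg <- if (n_fg > 0L) draw_fg_flags(n_fg, rates) else
      matrix(integer(0), 0L, length(pn), dimnames = list(NULL, pn))
    flags_rg <- matrix(0L, n_rg, length(pn), dimnames = list(NULL, pn))
    par <- demographic_params()
    demo_rg <- draw_demographics(n_rg, par$rg)
    demo_fg <- draw_demographics(n_fg, par$fg)
    feat_rg <- draw_features(n_rg, spec, "rg", flags_rg)
    feat_fg <- draw_features(n_fg, spec, "fg", flags_fg)

    build <- function(demo, flags, feats, status, prefix) {
      n <- nrow(demo)
      if (n == 0L) {
        out <- cbind(data.frame(id = character(0)), demo,
                     data.frame(frailty_status = integer(0)),
                     as.data.frame(flags), as.data.frame(feats))
        return(out)
      }
      cbind(data.frame(id = sprintf("%s%03d", prefix, seq_len(n)),
                       stringsAsFactors = FALSE),
            demo,
            data.frame(frailty_status = rep(status, n)),
            as.data.frame(flags), as.data.frame(feats))
    }
    cohort <- rbind(build(demo_rg, flags_rg, feat_rg, 0L, "RG"),
                    build(demo_fg, flags_fg, feat_fg, 1L, "FG"))
    rownames(cohort) <- NULL
    class(cohort) <- c("frail_cohort", "data.frame")
    cohort
  })
}

#' @export
print.frail_cohort <- function(x, ...) {
  cat(sprintf("<frail_cohort> %d participants (%d robust, %d pre-frail/frail)\n",
              nrow(x), sum(x$frailty_status == 0L), sum(x$frailty_status == 1L)))
  NextMethod()
}
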