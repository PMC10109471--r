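# Potential of mean force from umbrella-window samples
#
# Self-consistent WHAM reconstruction, bootstrap errors, binding-energy
# readout and laterally-restrained profiles. Units: order parameter in
# Angstrom, energies in kJ/mol, spring constants in kJ/mol/nm^2 (converted
# internally: bias = 0.5 k ((xi - xi0)/10)^2).

BOLTZ_KJ <- 0.0083144621  # kJ mol^-1 K^-1

validate_windows <- function(samples, min_samples = 50) {
  need <- c("window", "center", "k", "xi")
  if (!all(need %in% names(samples)))
    abort("umbrella samples need columns: window, center, k, xi")
  if (any(samples$k < 0)) abort("spring constants must be >= 0")
  cnt <- table(samples$window)
  if (any(cnt < min_samples))
    abort(paste0("window(s) ", paste(names(cnt)[cnt < min_samples],
                                     collapse = ", "),
                 " have fewer than ", min_samples, " samples"))
  invisible(samples)
}

window_meta <- function(samples) {
  distinct(samples, .data$window, .data$center, .data$k) %>%
    arrange(.data$center)
}

wham_grid <- function(samples, bins = NULL) {
  lo <- min(samples$xi); hi <- max(samples$xi)
  if (is.null(bins)) {
    centers <- sort(unique(samples$center))
    width <- if (length(centers) > 1) min(diff(centers)) / 5 else
      (hi - lo) / 30
    bins <- max(10L, ceiling((hi - lo) / width))
  }
  breaks <- seq(lo, hi, length.out = bins + 1)
  breaks[length(breaks)] <- hi + 1e-9
  list(breaks = breaks, mid = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

# core reconstruction on a fixed grid; returns G (kJ/mol, min 0) and f_i
wham_core <- function(samples, grid, temperature, tol, max_iter) {
  kT <- BOLTZ_KJ * temperature
  meta <- window_meta(samples)
  nw <- nrow(meta)
  nb <- length(grid$mid)
  counts <- matrix(0, nw, nb)
  Ntot <- numeric(nw)
  for (i in seq_len(nw)) {
    xi <- samples$xi[samples$window == meta$window[i]]
    h <- graphics::hist(xi, breaks = grid$breaks, plot = FALSE)
    counts[i, ] <- h$counts
    Ntot[i] <- length(xi)
  }
  # adjacent windows must share an occupied bin
  if (nw > 1) {
    for (i in seq_len(nw - 1)) {
      if (!any(counts[i, ] > 0 & counts[i + 1, ] > 0))
        abort(paste0("umbrella windows at centers ", meta$center[i], " and ",
                     meta$center[i + 1],
                     " do not overlap (no shared occupied bin)"))
    }
  }
  bias <- outer(seq_len(nw), seq_len(nb), function(i, b)
    0.5 * meta$k[i] * ((grid$mid[b] - meta$center[i]) / 10)^2)
  nsum <- colSums(counts)
  f <- numeric(nw)
  expb <- exp(-bias / kT)
  for (it in seq_len(max_iter)) {
    denom <- colSums(Ntot * exp(f / kT) * expb)
    rho <- ifelse(denom > 0, nsum / denom, 0)
    fnew <- -kT * log(colSums(t(expb) * rho))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
    if (it == max_iter)
      abort(paste0("WHAM did not converge in ", max_iter,
                   " iterations (residual ", signif(delta, 3), " kJ/mol)"))
  }
  denom <- colSums(Ntot * exp(f / kT) * expb)
  rho <- ifelse(denom > 0, nsum / denom, NA_real_)
  G <- -kT * log(rho)
  G <- G - min(G, na.rm = TRUE)
  list(G = G, f = f, rho = rho, counts = nsum)
}

#' WHAM reconstruction of a PMF
#'
#' Self-consistent weighted-histogram solution over the pooled samples of
#' all umbrella windows: the window free-energy constants f_i are iterated
#' to convergence, the unbiased density is recovered, and
#' G(xi) = -kT ln rho(xi) is reported shifted so its minimum is zero.
#'
#' @param samples Tibble of window samples: columns window (id), center
#'   (Angstrom), k (kJ/mol/nm^2), xi (Angstrom). Windows need >= 50 samples.
#' @param temperature Kelvin (default 298).
#' @param bins Number of histogram bins; default: window spacing / 5.
#' @param tol Convergence tolerance on f_i (kJ/mol).
#' @param max_iter Iteration cap.
#' @return A `pmf_curve`: list with `curve` (tibble xi, G, n_samples),
#'   `f` (window constants), `temperature`, `breaks`.
#' @export
wham <- function(samples, temperature = 298, bins = NULL, tol = 1e-6,
                 max_iter = 1e5) {
  validate_windows(samples)
  grid <- wham_grid(samples, bins)
  core <- wham_core(samples, grid, temperature, tol, max_iter)
  structure(list(curve = tibble(xi = grid$mid, G = core$G,
                                n_samples = core$counts),
                 f = core$f, temperature = temperature,
                 breaks = grid$breaks),
            class = "pmf_curve")
}

#' @export
print.pmf_curve <- function(x, ...) {
  ok <- is.finite(x$curve$G)
  cat("<pmf_curve> ", sum(ok), " occupied bins over xi in [",
      signif(min(x$curve$xi), 4), ", ", signif(max(x$curve$xi), 4),
      "] A; max G = ", signif(max(x$curve$G[ok]), 4), " kJ/mol\n", sep = "")
  invisible(x)
}

#' Bootstrap standard errors of a PMF
#'
#' Resamples the xi values within each window with replacement — in circular
#' blocks of `block` consecutive samples, which preserves the serial
#' correlation of the window time series — repeats the WHAM reconstruction
#' on the same bin grid, and reports the per-bin standard deviation of G
#' over the replicates. Deterministic for a given seed.
#'
#' @inheritParams wham
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Random seed.
#' @param block Block length for the moving-block resampling (1 = plain
#'   i.i.d. bootstrap).
#' @return Tibble: xi, se (kJ/mol; NA where the original curve is undefined).
#' @export
bootstrap_error <- function(samples, temperature = 298, B = 100, seed = 1,
                            bins = NULL, block = 20, tol = 1e-6,
                            max_iter = 1e5) {
  if (B < 2) abort("need at least 2 bootstrap replicates")
  stopifnot(block >= 1)
  validate_windows(samples)
  grid <- wham_grid(samples, bins)
  set.seed(seed)
  split_idx <- split(seq_len(nrow(samples)), samples$window)
  draw <- function(ii) {
    n <- length(ii)
    b <- min(block, n)
    starts <- sample.int(n, ceiling(n / b), replace = TRUE)
    pos <- (rep(starts, each = b) + rep(seq_len(b) - 1L,
                                        length(starts)) - 1L) %% n + 1L
    ii[pos[seq_len(n)]]
  }
  reps <- matrix(NA_real_, length(grid$mid), B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(split_idx, draw))
    core <- wham_core(samples[idx, ], grid, temperature, tol, max_iter)
    reps[, b] <- core$G
  }
  tibble(xi = grid$mid, se = apply(reps, 1, sd))
}

#' Binding energy from a PMF curve
#'
#' G at the largest adequately sampled xi; since the curve minimum is zero
#' this equals the well depth. Bins with fewer than `min_count` samples are
#' ignored (edge bins are noise-dominated). The tail must be a plateau: the
#' |slope| of a linear fit over the last five retained bins must be below
#' `slope_tol`, otherwise the value is returned flagged (with a warning).
#' The reported value is the mean G of the last three retained bins.
#'
#' @param curve A `pmf_curve` from [wham()].
#' @param slope_tol Plateau slope tolerance (kJ/mol per Angstrom).
#' @param min_count Minimum per-bin sample count for the tail readout.
#' @return List: `value` (kJ/mol), `plateau` (logical).
#' @export
binding_energy <- function(curve, slope_tol = 1, min_count = 20) {
  stopifnot(inherits(curve, "pmf_curve"))
  cv <- filter(curve$curve, is.finite(.data$G),
               .data$n_samples >= min_count)
  if (nrow(cv) < 5) abort("too few adequately sampled bins")
  tail5 <- cv[(nrow(cv) - 4):nrow(cv), ]
  slope <- abs(stats::coef(stats::lm(G ~ xi, data = tail5))[2])
  plateau <- slope < slope_tol
  if (!plateau)
    warn(paste0("PMF tail is not a plateau (|slope| ", signif(slope, 3),
                " kJ/mol/A): binding energy flagged"))
  list(value = mean(cv$G[(nrow(cv) - 2):nrow(cv)]),
       plateau = unname(plateau))
}

#' Laterally-restrained PMF profile
#'
#' WHAM reconstruction along a signed lateral-displacement order parameter,
#' annotated with the arrangement loci of the classification module's offset
#' convention (Arr-A head-on at 0, the canonical Arr-B offset at +/- 9 A,
#' the Arr-D offset signature at +/- 15 A).
#'
#' @inheritParams wham
#' @return A `pmf_curve` with an extra `annotations` tibble (label, offset).
#' @export
restrained_profile <- function(samples, temperature = 298, bins = NULL,
                               tol = 1e-6, max_iter = 1e5) {
  out <- wham(samples, temperature, bins, tol, max_iter)
  out$annotations <- tibble(
    label = c("Arr-A", "Arr-B", "Arr-B", "Arr-D", "Arr-D"),
    offset = c(0, -9, 9, -ARR_D_OFFSET, ARR_D_OFFSET))
  out
}

#' Read / write umbrella-window samples as TSV
#'
#' Columns: window, center, k, xi (tab-separated, header included).
#'
#' @param path File path.
#' @return [read_umbrella()]: samples tibble; [write_umbrella()]: the path,
#'   invisibly.
#' @export
read_umbrella <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_windows(tibble(window = df$window, center = as.numeric(df$center),
                          k = as.numeric(df$k), xi = as.numeric(df$xi)),
                   min_samples = 1)
}

#' @rdname read_umbrella
#' @param samples Samples tibble (window, center, k, xi).
#' @export
write_umbrella <- function(samples, path) {
  utils::write.table(samples[, c("window", "center", "k", "xi")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
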