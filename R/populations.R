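# Dimer enumeration, near/bulk population selection, (r, theta, psi)
# histograms, marginals, differential probability maps, free-energy maps.

#' Enumerate solute dimers of an ensemble
#'
#' All solute pairs with minimum-image ring-centroid distance below
#' `r_max` are scored with [dimer_params()], classified, and returned as a
#' data frame, one row per (frame, pair).
#'
#' @param ens an [ensemble()]
#' @param thresholds a [classifier_thresholds()]
#' @param r_max pair inclusion radius (A)
#' @return data.frame with columns `frame`, `id_a`, `id_b`, `r`, `theta`,
#'   `psi`, `hbond`, `class`, `polarity`, `dist_mod_a`, `dist_mod_b`
#'   (minimum heavy-atom distances to the modifier; `Inf` without one)
#' @export
enumerate_dimers <- function(ens, thresholds = classifier_thresholds(),
                             r_max = 8.0) {
  rows <- vector("list", n_frames(ens))
  for (fi in seq_len(n_frames(ens))) {
    fr <- ens$frames[[fi]]
    sol <- frame_solutes(fr)
    if (length(sol) < 2L) next
    mod <- frame_modifier(fr)
    mod_heavy <- if (is.null(mod)) NULL else heavy_xyz(mod)
    cents <- t(vapply(sol, ring_centroid, numeric(3)))
    dmod <- if (is.null(mod_heavy)) rep(Inf, length(sol)) else
      vapply(sol, function(m)
        min_cross_dist(heavy_xyz(m), mod_heavy, fr$box), numeric(1))
    dmat <- cross_dist(cents, cents, fr$box)
    pairs <- which(upper.tri(dmat) & dmat <= r_max, arr.ind = TRUE)
    if (!nrow(pairs)) next
    recs <- vector("list", nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      g <- dimer_params(sol[[i]], sol[[j]], box = fr$box,
                        frame_index = fr$frame_index)
      hb <- hbond_contact(sol[[i]], sol[[j]],
                          cutoff = thresholds$hbond_contact_max,
                          box = fr$box)
      cls <- classify_conformer(g, thresholds, hb)
      pol <- if (cls == "stacked")
        stacking_polarity(sol[[i]], sol[[j]]) else "undefined"
      recs[[p]] <- data.frame(
        frame = fr$frame_index,
        id_a = min(g$pair_ids), id_b = max(g$pair_ids),
        r = g$r, theta = g$theta, psi = g$psi, hbond = hb,
        class = cls, polarity = pol,
        dist_mod_a = dmod[i], dist_mod_b = dmod[j])
    }
    rows[[fi]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(), id_a = integer(), id_b = integer(),
                      r = numeric(), theta = numeric(), psi = numeric(),
                      hbond = logical(), class = character(),
                      polarity = character(), dist_mod_a = numeric(),
                      dist_mod_b = numeric())
  rownames(out) <- NULL
  out
}

#' Near/bulk population selection rule
#'
#' @param r_cut_modifier near cutoff: minimum heavy-atom distance from a
#'   solute to any modifier heavy atom (A)
#' @param membership `"either_member"` (a dimer is near when at least one
#'   member is within the cutoff; the default, matching a per-molecule
#'   vicinity criterion) or `"both_members"` (both members required;
#'   straddling dimers are excluded from both populations)
#' @param r_max dimer pair-inclusion radius (A)
#' @return object of class `population_selection`
#' @export
population_selection <- function(r_cut_modifier = 4.0,
                                 membership = c("either_member",
                                                "both_members"),
                                 r_max = 8.0) {
  if (r_cut_modifier <= 0) stop("r_cut_modifier must be positive")
  structure(list(r_cut_modifier = r_cut_modifier,
                 membership = match.arg(membership), r_max = r_max),
            class = "population_selection")
}

#' Split enumerated dimers into near-modifier and bulk populations
#'
#' @param ens an [ensemble()] (or a precomputed [enumerate_dimers()] data
#'   frame via `dimers`)
#' @param sel a [population_selection()]
#' @param thresholds a [classifier_thresholds()]
#' @param dimers optional precomputed dimer table
#' @param require_near error when no modifier is present? (set `FALSE` for
#'   bulk-only ensembles, which return an empty near set)
#' @return list with data.frames `near`, `bulk`, `excluded`, and `all`
#' @export
select_populations <- function(ens, sel = population_selection(),
                               thresholds = classifier_thresholds(),
                               dimers = NULL, require_near = TRUE) {
  dim_df <- dimers %||% enumerate_dimers(ens, thresholds, r_max = sel$r_max)
  has_mod <- any(is.finite(dim_df$dist_mod_a)) ||
    any(vapply(ens$frames, function(fr) !is.null(frame_modifier(fr)),
               logical(1)))
  if (!has_mod && require_near)
    stop("selection error: near population requested but no modifier ",
         "is present in the ensemble")
  in_a <- dim_df$dist_mod_a <= sel$r_cut_modifier
  in_b <- dim_df$dist_mod_b <= sel$r_cut_modifier
  if (sel$membership == "both_members") {
    near <- in_a & in_b
    bulk <- !in_a & !in_b
  } else {
    near <- in_a | in_b
    bulk <- !near
  }
  excluded <- !(near | bulk)
  list(near = dim_df[near, , drop = FALSE],
       bulk = dim_df[bulk, , drop = FALSE],
       excluded = dim_df[excluded, , drop = FALSE],
       all = dim_df)
}

#' Bin-edge axes for conformer histograms
#'
#' Defaults: r in \[2, 8\] A at 0.2 A; theta and psi in \[0, pi\] at pi/36.
#'
#' @param r_edges,theta_edges,psi_edges increasing bin-edge vectors
#' @return list of class `conformer_axes`
#' @export
conformer_axes <- function(r_edges = seq(2, 8, by = 0.2),
                           theta_edges = seq(0, pi, length.out = 37),
                           psi_edges = seq(0, pi, length.out = 37)) {
  for (e in list(r_edges, theta_edges, psi_edges))
    if (length(e) < 2L || any(diff(e) <= 0))
      stop("bin edges must be increasing with at least two values")
  structure(list(r = r_edges, theta = theta_edges, psi = psi_edges),
            class = "conformer_axes")
}

# Half-open [lo, hi) binning, last bin closed; values outside return NA.
bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1L | i > length(edges) - 1L] <- NA_integer_
  i
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' 3D (r, theta, psi) conformer histogram
#'
#' Exact counting with half-open bins \[lo, hi) (last bin closed);
#' `probability` normalizes counts by the total number of observations.
#' Observations falling outside the axes are dropped with a warning.
#'
#' @param dimers an [enumerate_dimers()]-style data frame
#' @param axes a [conformer_axes()]
#' @return object of class `conformer_histogram`: `axes`, `counts` (3D
#'   array), `probability`, `n` (total observations counted)
#' @export
histogram3d <- function(dimers, axes = conformer_axes()) {
  if (!nrow(dimers)) stop("empty dimer list: cannot build a histogram")
  ir <- bin_index(dimers$r, axes$r)
  it <- bin_index(dimers$theta, axes$theta)
  ip <- bin_index(dimers$psi, axes$psi)
  keep <- !(is.na(ir) | is.na(it) | is.na(ip))
  if (any(!keep))
    warning(sum(!keep), " observation(s) outside the histogram axes dropped")
  dims <- c(length(axes$r) - 1L, length(axes$theta) - 1L,
            length(axes$psi) - 1L)
  counts <- array(0L, dims)
  if (any(keep)) {
    lin <- (ip[keep] - 1L) * dims[1] * dims[2] + (it[keep] - 1L) * dims[1] +
      ir[keep]
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(tab, dims)
  }
  n <- sum(counts)
  if (n == 0L) stop("empty histogram: no observation fell inside the axes")
  structure(list(axes = axes, counts = counts, probability = counts / n,
                 n = n),
            class = "conformer_histogram")
}

# Marginalize a conformer_histogram onto the named axes (1 or 2 of
# "r","theta","psi"), preserving axis order r, theta, psi.
marginalize_histogram <- function(h, axes_names) {
  ax_order <- c("r", "theta", "psi")
  keep <- match(axes_names, ax_order)
  if (anyNA(keep)) stop("unknown axis name(s): ",
                        paste(axes_names[is.na(keep)], collapse = ", "))
  keep <- sort(keep)
  prob <- apply(h$probability, keep, sum)
  counts <- apply(h$counts, keep, sum)
  list(axes_names = ax_order[keep],
       edges = h$axes[ax_order[keep]],
       probability = prob, counts = counts, n = h$n)
}

#' Differential probability map between two populations
#'
#' Marginalizes both histograms onto two axes and subtracts bulk from near
#' per bin. Values sum to 0 (difference of two normalized distributions on
#' identical support).
#'
#' @param near,bulk [histogram3d()] results on identical axes
#' @param axes_names two of `"r"`, `"theta"`, `"psi"`
#' @return object of class `differential_map`: `axes_names`, `edges`,
#'   `values` (signed probability differences)
#' @export
differential_map <- function(near, bulk, axes_names = c("r", "psi")) {
  if (length(axes_names) != 2L) stop("a differential map needs two axes")
  for (ax in c("r", "theta", "psi"))
    if (!isTRUE(all.equal(near$axes[[ax]], bulk$axes[[ax]])))
      stop("contract error: near and bulk histograms use different '",
           ax, "' bin edges")
  mn <- marginalize_histogram(near, axes_names)
  mb <- marginalize_histogram(bulk, axes_names)
  structure(list(axes_names = mn$axes_names, edges = mn$edges,
                 values = mn$probability - mb$probability),
            class = "differential_map")
}

#' psi marginal of a conformer histogram
#'
#' @param h a [histogram3d()] result
#' @return list with `edges`, `centers`, `probability` (sums to 1), and
#'   `peak` (bin center of the modal bin)
#' @export
psi_marginal <- function(h) {
  m <- marginalize_histogram(h, "psi")
  centers <- bin_centers(m$edges$psi)
  list(edges = m$edges$psi, centers = centers, probability = m$probability,
       peak = centers[which.max(m$probability)])
}

#' Probability mass of a psi band
#'
#' Sums bins whose centers fall within `halfwidth` of `center`; when
#' `center` is 0 or pi the band is mirrored onto both stacking poles.
#'
#' @param marginal a [psi_marginal()] result (or any list with `centers`
#'   and `probability`)
#' @param center band center (radians)
#' @param halfwidth band halfwidth (radians)
#' @return probability mass in \[0, 1\]
#' @export
psi_band_mass <- function(marginal, center = pi / 2, halfwidth = pi / 9) {
  x <- marginal$centers
  sel <- abs(x - center) <= halfwidth
  if (center == 0 || isTRUE(all.equal(center, pi)))
    sel <- x <= halfwidth | x >= pi - halfwidth
  sum(marginal$probability[sel])
}

#' Signed band mass of a differential map along its psi axis
#'
#' Sums the signed probability differences of a [differential_map()] over
#' the psi bins whose centers fall within the band (mirrored onto both
#' stacking poles when `center` is 0 or pi).
#'
#' @param map a [differential_map()] with a psi axis
#' @param center band center (radians)
#' @param halfwidth band halfwidth (radians)
#' @return signed probability mass
#' @export
differential_band_mass <- function(map, center = pi / 2,
                                   halfwidth = pi / 9) {
  if (!"psi" %in% map$axes_names)
    stop("map has no psi axis")
  k <- which(map$axes_names == "psi")
  centers <- bin_centers(map$edges$psi)
  sel <- abs(centers - center) <= halfwidth
  if (center == 0 || isTRUE(all.equal(center, pi)))
    sel <- centers <= halfwidth | centers >= pi - halfwidth
  if (k == 1L) sum(map$values[sel, ]) else sum(map$values[, sel])
}

#' Free-energy map from a 2D marginal distribution
#'
#' Values are -ln(p) in kT units, shifted so the global minimum over
#' occupied bins is 0; empty bins are masked as `NA` (undefined), never a
#' large number.
#'
#' @param h a [histogram3d()] result or a [marginalize_histogram()] 2D
#'   marginal
#' @param axes_names two axes used when `h` is a 3D histogram
#' @return object of class `free_energy_map`: `axes_names`, `edges`,
#'   `values` (kT)
#' @export
free_energy_map <- function(h, axes_names = c("r", "theta")) {
  m <- if (inherits(h, "conformer_histogram"))
    marginalize_histogram(h, axes_names) else h
  p <- m$probability
  if (all(p == 0)) stop("all-empty distribution: free energy undefined")
  v <- ifelse(p > 0, -log(p), NA_real_)
  v <- v - min(v, na.rm = TRUE)
  structure(list(axes_names = m$axes_names, edges = m$edges, values = v),
            class = "free_energy_map")
}
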