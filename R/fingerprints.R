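# Crystal-derived geometric fingerprints and conforming-dimer probability.
#
# A fingerprint is a (r0, theta0, psi0) target region with a tolerance box;
# dimers whose parameters fall inside any selected box are "crystal
# conforming". Fingerprints are extracted from an idealized (or
# user-supplied) lattice frame by enumerating neighbor pairs and greedily
# agglomerating them in the tolerance-scaled max metric.

#' Fingerprint matching tolerances
#'
#' Defaults (0.5 A, 15 deg, 15 deg); always echoed into reports.
#'
#' @param dr,dtheta,dpsi half-widths of the tolerance box (A, radians)
#' @return list of class `fingerprint_tolerances`
#' @export
fingerprint_tolerances <- function(dr = 0.5, dtheta = 15 * pi / 180,
                                   dpsi = 15 * pi / 180) {
  if (dr <= 0 || dtheta <= 0 || dpsi <= 0) stop("tolerances must be > 0")
  structure(list(dr = dr, dtheta = dtheta, dpsi = dpsi),
            class = "fingerprint_tolerances")
}

# scaled max-metric distance between a geometry row and a fingerprint center
.fp_metric <- function(r, theta, psi, fp, tol) {
  pmax(abs(r - fp$r0) / tol$dr, abs(theta - fp$theta0) / tol$dtheta,
       abs(psi - fp$psi0) / tol$dpsi)
}

#' Extract dimer fingerprints from a crystal lattice frame
#'
#' Enumerates all solute pairs within `neighbor_cutoff`, computes their
#' (r, theta, psi), and clusters them greedily: a pair joins the first
#' fingerprint whose center lies within the tolerance box, otherwise founds
#' a new fingerprint (center = its own geometry). Labels follow the
#' conformer classification of the cluster center (`stacked` carries
#' polarity `parallel`, the crystal's stacking mode; coplanar modes are
#' numbered).
#'
#' @param lattice an [md_frame()] with >= 2 solute molecules
#' @param neighbor_cutoff centroid-distance cutoff for lattice neighbors (A)
#' @param tol a [fingerprint_tolerances()]
#' @param thresholds a [classifier_thresholds()] used for labeling
#' @return data.frame of class `crystal_fingerprints`: `label`, `r0`,
#'   `theta0`, `psi0`, `dr`, `dtheta`, `dpsi`, `multiplicity`, `polarity`
#' @export
extract_fingerprints <- function(lattice, neighbor_cutoff = 7.5,
                                 tol = fingerprint_tolerances(),
                                 thresholds = classifier_thresholds()) {
  sol <- frame_solutes(lattice)
  if (length(sol) < 2L)
    stop("fingerprint extraction needs a lattice with >= 2 solute molecules")
  cents <- t(vapply(sol, ring_centroid, numeric(3)))
  dmat <- cross_dist(cents, cents, lattice$box)
  pairs <- which(upper.tri(dmat) & dmat <= neighbor_cutoff, arr.ind = TRUE)
  if (!nrow(pairs))
    stop("empty result: no lattice pairs within the neighbor cutoff")
  fps <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    g <- dimer_params(sol[[i]], sol[[j]], box = lattice$box)
    hit <- 0L
    for (k in seq_along(fps)) {
      if (.fp_metric(g$r, g$theta, g$psi, fps[[k]], tol) < 1) { hit <- k; break }
    }
    if (hit) {
      fps[[hit]]$multiplicity <- fps[[hit]]$multiplicity + 1L
    } else {
      hb <- hbond_contact(sol[[i]], sol[[j]],
                          cutoff = thresholds$hbond_contact_max,
                          box = lattice$box)
      cls <- classify_conformer(g, thresholds, hb)
      pol <- if (cls == "stacked") stacking_polarity(sol[[i]], sol[[j]])
        else "undefined"
      fps[[length(fps) + 1L]] <- list(r0 = g$r, theta0 = g$theta,
                                      psi0 = g$psi, class = cls,
                                      polarity = pol, multiplicity = 1L)
    }
  }
  n_cop <- 0L
  label <- character(length(fps))
  for (k in seq_along(fps)) {
    if (fps[[k]]$class == "coplanar") {
      n_cop <- n_cop + 1L
      label[k] <- paste0("coplanar-mode-", n_cop)
    } else if (fps[[k]]$class == "stacked") {
      label[k] <- if (fps[[k]]$r0 <= 5.5) "stacked" else
        paste0("stacked-r", round(fps[[k]]$r0, 1))
    } else label[k] <- paste0("other-", k)
  }
  out <- data.frame(
    label = label,
    r0 = vapply(fps, `[[`, numeric(1), "r0"),
    theta0 = vapply(fps, `[[`, numeric(1), "theta0"),
    psi0 = vapply(fps, `[[`, numeric(1), "psi0"),
    dr = tol$dr, dtheta = tol$dtheta, dpsi = tol$dpsi,
    multiplicity = vapply(fps, `[[`, integer(1), "multiplicity"),
    polarity = vapply(fps, `[[`, character(1), "polarity"))
  class(out) <- c("crystal_fingerprints", "data.frame")
  out
}

# Select the fingerprints used for conformity testing.
.select_fps <- function(fps, use = c("coplanar_only", "all")) {
  use <- match.arg(use)
  if (use == "coplanar_only")
    fps <- fps[grepl("^coplanar", fps$label), , drop = FALSE]
  if (!nrow(fps)) stop("no fingerprints selected for conformity testing")
  fps
}

#' Which dimers conform to a fingerprint set?
#'
#' @param dimers an [enumerate_dimers()]-style data frame
#' @param fps a [extract_fingerprints()] table (or one read back from disk)
#' @param use `"coplanar_only"` (default: the promotion mechanism concerns
#'   coplanar arrangements) or `"all"`
#' @return logical vector, one element per dimer row
#' @export
conforms_to_fingerprints <- function(dimers, fps,
                                     use = c("coplanar_only", "all")) {
  fps <- .select_fps(fps, use)
  ok <- rep(FALSE, nrow(dimers))
  for (k in seq_len(nrow(fps))) {
    ok <- ok | (abs(dimers$r - fps$r0[k]) <= fps$dr[k] &
                  abs(dimers$theta - fps$theta0[k]) <= fps$dtheta[k] &
                  abs(dimers$psi - fps$psi0[k]) <= fps$dpsi[k])
  }
  ok
}

#' Probability of crystal-conforming dimers, normalized to bulk
#'
#' @param near,bulk dimer data frames for the two populations (non-empty)
#' @param fps fingerprint table
#' @param use see [conforms_to_fingerprints()]
#' @return object of class `conforming_report`: `p_near`, `p_bulk`,
#'   `enrichment` (`p_near / p_bulk`, `NA` when `p_bulk` is 0), counts, and
#'   the echoed fingerprints
#' @export
conforming_probability <- function(near, bulk, fps,
                                   use = c("coplanar_only", "all")) {
  if (!nrow(near)) stop("empty dimer list for population 'near'")
  if (!nrow(bulk)) stop("empty dimer list for population 'bulk'")
  p_near <- mean(conforms_to_fingerprints(near, fps, use))
  p_bulk <- mean(conforms_to_fingerprints(bulk, fps, use))
  structure(list(p_near = p_near, p_bulk = p_bulk,
                 enrichment = if (p_bulk > 0) p_near / p_bulk else NA_real_,
                 n_near = nrow(near), n_bulk = nrow(bulk),
                 use = match.arg(use), fingerprints = fps),
            class = "conforming_report")
}

#' @export
print.conforming_report <- function(x, ...) {
  cat(sprintf(
    "<conforming_report> p_near = %.4f (n = %d), p_bulk = %.4f (n = %d), enrichment = %s\n",
    x$p_near, x$n_near, x$p_bulk, x$n_bulk,
    if (is.na(x$enrichment)) "undefined" else sprintf("%.3f", x$enrichment)))
  invisible(x)
}

#' Rank modifiers by conforming-dimer enrichment
#'
#' @param reports named list of [conforming_probability()] reports
#' @return data.frame sorted by enrichment (descending), ties broken by
#'   `p_near` then name
#' @export
rank_modifiers <- function(reports) {
  if (!length(reports)) stop("no reports to rank")
  nm <- names(reports) %||% as.character(seq_along(reports))
  df <- data.frame(
    modifier = nm,
    p_near = vapply(reports, `[[`, numeric(1), "p_near"),
    p_bulk = vapply(reports, `[[`, numeric(1), "p_bulk"),
    enrichment = vapply(reports, `[[`, numeric(1), "enrichment"))
  df <- df[order(-df$enrichment, -df$p_near, df$modifier), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Write fingerprints to a structured text file
#' @param fps fingerprint table
#' @param path output path (YAML)
#' @export
write_fingerprints <- function(fps, path) {
  recs <- lapply(seq_len(nrow(fps)), function(k) as.list(fps[k, ]))
  yaml::write_yaml(list(fingerprints = recs), path, precision = 15)
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#' @param path input path
#' @return fingerprint data.frame
#' @export
read_fingerprints <- function(path) {
  recs <- yaml::read_yaml(path)$fingerprints
  if (is.null(recs)) stop("no fingerprints found in ", path)
  out <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  class(out) <- c("crystal_fingerprints", "data.frame")
  out
}
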