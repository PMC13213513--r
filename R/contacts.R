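# Modifier-solute contact frequency tables, conditional dimer splitting by
# a named modifier hydrogen, and hydrogen-bond mode timelines.

#' Hydrogen / heavy-atom contact frequency table
#'
#' One row per labeled modifier hydrogen, one column per solute acceptor
#' atom type. Each cell is the fraction of frames in which the minimum
#' distance from that hydrogen to that acceptor type, over all solute
#' copies, is below `r_cut` (per-frame any-copy criterion; set
#' `per_copy = TRUE` to average the indicator over solute copies instead).
#'
#' @param ens an [ensemble()] with one modifier per frame
#' @param r_cut contact cutoff (A), default 2.5
#' @param per_copy average over solute copies instead of any-copy?
#' @return matrix of contact frequencies in \[0, 1\]
#' @export
contact_frequency <- function(ens, r_cut = HBOND_CUTOFF, per_copy = FALSE) {
  fr1 <- ens$frames[[1]]
  mod <- frame_modifier(fr1)
  if (is.null(mod)) stop("topology error: ensemble has no modifier")
  hyd <- mod$spec$hydrogen_atoms
  if (!length(hyd)) stop("topology error: modifier has no labeled hydrogens")
  sol1 <- frame_solutes(fr1)
  if (!length(sol1)) stop("ensemble has no solutes")
  acc <- sol1[[1]]$spec$acceptor_atoms
  if (!length(acc)) stop("topology error: solute has no labeled acceptors")
  tab <- matrix(0, length(hyd), length(acc), dimnames = list(hyd, acc))
  nf <- n_frames(ens)
  denom <- 0
  for (fi in seq_len(nf)) {
    fr <- ens$frames[[fi]]
    m <- frame_modifier(fr)
    hx <- atom_xyz(m, hyd)
    sols <- frame_solutes(fr)
    per_sol <- lapply(sols, function(s)
      cross_dist(hx, atom_xyz(s, acc), fr$box))  # hyd x acc each
    if (per_copy) {
      for (s in per_sol) tab <- tab + (s <= r_cut)
      denom <- denom + length(per_sol)
    } else {
      dmin <- Reduce(pmin, per_sol)
      tab <- tab + (dmin <= r_cut)
      denom <- denom + 1
    }
  }
  tab / denom
}

#' Split near-modifier dimers by contact with a named modifier hydrogen
#'
#' A dimer belongs to the contacting set in a frame iff either member has
#' an acceptor atom within `r_cut` of the named hydrogen in that frame.
#' The two subsets partition the input dimer table.
#'
#' @param ens an [ensemble()] with one modifier per frame
#' @param dimers dimer table (e.g. the `near` population from
#'   [select_populations()])
#' @param hydrogen_label modifier hydrogen name, e.g. `"H13"`
#' @param r_cut contact cutoff (A)
#' @return list with data.frames `contacting` and `noncontacting`
#' @export
conditional_dimer_split <- function(ens, dimers, hydrogen_label = "H13",
                                    r_cut = HBOND_CUTOFF) {
  mod1 <- frame_modifier(ens$frames[[1]])
  if (is.null(mod1)) stop("ensemble has no modifier")
  if (!hydrogen_label %in% mod1$spec$hydrogen_atoms)
    stop("unknown modifier hydrogen label: ", hydrogen_label)
  frame_of <- match(dimers$frame,
                    vapply(ens$frames, `[[`, integer(1), "frame_index"))
  contacting <- logical(nrow(dimers))
  for (row in seq_len(nrow(dimers))) {
    fr <- ens$frames[[frame_of[row]]]
    hx <- atom_xyz(frame_modifier(fr), hydrogen_label)
    ok <- FALSE
    for (id in c(dimers$id_a[row], dimers$id_b[row])) {
      mol <- Find(function(m) m$molecule_id == id, fr$molecules)
      acc <- mol$spec$acceptor_atoms
      if (!length(acc)) next
      if (min_cross_dist(hx, atom_xyz(mol, acc), fr$box) <= r_cut) {
        ok <- TRUE; break
      }
    }
    contacting[row] <- ok
  }
  list(contacting = dimers[contacting, , drop = FALSE],
       noncontacting = dimers[!contacting, , drop = FALSE])
}

#' Hydrogen-bond mode timeline of a tracked solute pair
#'
#' Per frame, the mode label is the sorted set of (donor hydrogen,
#' acceptor) atom-name pairs within `r_cut` between the two molecules
#' (`"none"` when empty); the transition count is the number of
#' consecutive-frame label changes.
#'
#' @param ens an [ensemble()]
#' @param pair_ids the two molecule ids to track
#' @param r_cut hydrogen-bond contact cutoff (A)
#' @return list with `labels` (character, one per frame) and `transitions`
#' @export
hbond_mode_timeline <- function(ens, pair_ids, r_cut = HBOND_CUTOFF) {
  if (length(pair_ids) != 2L) stop("pair_ids must name two molecules")
  labels <- character(n_frames(ens))
  for (fi in seq_len(n_frames(ens))) {
    fr <- ens$frames[[fi]]
    mols <- lapply(pair_ids, function(id)
      Find(function(m) m$molecule_id == id, fr$molecules))
    if (any(vapply(mols, is.null, logical(1))))
      stop("pair (", pair_ids[1], ", ", pair_ids[2], ") absent in frame ",
           fr$frame_index)
    modes <- character(0)
    for (k in 1:2) {
      don <- mols[[k]]; acc <- mols[[3 - k]]
      dh <- don$spec$hydrogen_atoms
      aa <- acc$spec$acceptor_atoms
      if (!length(dh) || !length(aa)) next
      dm <- cross_dist(atom_xyz(don, dh), atom_xyz(acc, aa), fr$box)
      hit <- which(dm <= r_cut, arr.ind = TRUE)
      if (nrow(hit))
        modes <- c(modes, paste0(dh[hit[, 1]], ">", aa[hit[, 2]]))
    }
    labels[fi] <- if (length(modes)) paste(sort(modes), collapse = "|")
      else "none"
  }
  list(labels = labels,
       transitions = sum(labels[-1] != labels[-length(labels)]))
}
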