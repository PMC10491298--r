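# DSSP-criteria secondary structure: backbone hydrogen bonds scored by the
# published electrostatic energy model, bridge patterns for beta-sheet
# (antiparallel and parallel, inter- and intramolecular) and n-turn
# patterns for 3-10/alpha/pi helices.  Simplified tie-breaking:
# beta beats helix beats other.

#' DSSP hydrogen-bond energy
#'
#' E = 0.42 * 0.20 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol;
#' the bond exists when E < -0.5 kcal/mol.
#'
#' @param C,O,N,H Positions (3-vectors or m x 3 matrices) of the acceptor
#'   C=O and donor N-H atoms.
#' @param box Cubic box side for minimum-image distances (NA for none).
#' @return List with `energy` (kcal/mol) and `bonded` (logical).
#' @export
dssp_hbond_energy <- function(C, O, N, H, box = NA) {
  as_m <- function(x) if (is.null(dim(x))) matrix(x, ncol = 3) else x
  C <- as_m(C); O <- as_m(O); N <- as_m(N); H <- as_m(H)
  dist1 <- function(a, b) {
    d <- .min_image(a - b, if (is.na(box)) NA else box)
    sqrt(rowSums(d * d))
  }
  rON <- dist1(O, N); rCH <- dist1(C, H)
  rOH <- dist1(O, H); rCN <- dist1(C, N)
  if (any(c(rON, rCH, rOH, rCN) == 0))
    stop("coincident atoms in DSSP hydrogen-bond energy")
  e <- 0.42 * 0.20 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  list(energy = e, bonded = e < -0.5)
}

# residue table for SS assignment: one row per non-water residue with
# atom ids for N,H,CA,C,O; `chain_pos` is the position along its chain.
.ss_residues <- function(system) {
  rm_ <- system$resmap
  rm_ <- rm_[rm_$res_name != "HOH", , drop = FALSE]
  rm_$gid <- seq_len(nrow(rm_))
  rm_$amino <- !(rm_$res_name %in% c("ACE", "NME"))
  rm_
}

#' DSSP-criteria secondary-structure assignment of one frame
#'
#' Backbone hydrogen bonds are scored with [dssp_hbond_energy()] (donor
#' N-H to acceptor C=O; same-residue and peptide-bond-neighbour pairs
#' excluded).  Beta bridges follow the DSSP antiparallel and parallel
#' patterns; a residue is a helix when it sits in two consecutive
#' i -> i+3, i -> i+4 or i -> i+5 turns.  Each amino residue receives one
#' label: "beta_anti_inter", "beta_anti_intra", "beta_para", "helix" or
#' "other" (beta beats helix beats other; antiparallel beats parallel).
#'
#' @param coords n x 3 coordinate matrix (a trajectory frame).
#' @param system `fp_system`.
#' @param box Cubic box side (defaults to the system's).
#' @return List: `labels` (data.frame residue table with `label` and
#'   bridge partner), `hbonds` (the justifying H-bond list).
#' @export
assign_ss <- function(coords, system, box = system$box) {
  res <- .ss_residues(system)
  nr <- nrow(res)
  need <- res$amino & (is.na(res$N) | is.na(res$H) | is.na(res$C) | is.na(res$O))
  if (any(need))
    stop("residue ", res$res_local[which(need)[1]], " of peptide ",
         res$mol_id[which(need)[1]], " lacks backbone sites")
  don <- which(!is.na(res$N) & !is.na(res$H))
  acc <- which(!is.na(res$C) & !is.na(res$O))
  bx <- if (is.null(box) || is.na(box)) NA else box

  # candidate pairs by O...N prefilter
  dON <- .dist_pbc(coords[res$O[acc], , drop = FALSE],
                   coords[res$N[don], , drop = FALSE], bx)
  hit <- which(dON < 5.2, arr.ind = TRUE)
  hb <- matrix(FALSE, nr, nr)  # hb[d, a]: donor NH of d bonds CO of a
  hbl <- NULL
  if (nrow(hit)) {
    ai <- acc[hit[, 1]]; di <- don[hit[, 2]]
    same <- ai == di
    nbr <- res$mol_id[ai] == res$mol_id[di] &
      abs(res$res_local[ai] - res$res_local[di]) == 1
    ok <- !(same | nbr)
    ai <- ai[ok]; di <- di[ok]
    if (length(ai)) {
      e <- dssp_hbond_energy(coords[res$C[ai], , drop = FALSE],
                             coords[res$O[ai], , drop = FALSE],
                             coords[res$N[di], , drop = FALSE],
                             coords[res$H[di], , drop = FALSE], bx)
      bnd <- e$bonded
      hb[cbind(di[bnd], ai[bnd])] <- TRUE
      hbl <- data.frame(donor = di[bnd], acceptor = ai[bnd],
                        energy = e$energy[bnd])
    }
  }

  # chain-neighbour helpers (gid of residue at chain_pos +/- 1, NA if absent)
  nxt <- rep(NA_integer_, nr); prv <- rep(NA_integer_, nr)
  for (g in seq_len(nr)) {
    cand <- which(res$mol_id == res$mol_id[g] &
                  res$res_local == res$res_local[g] + 1L)
    if (length(cand)) nxt[g] <- cand
    cand <- which(res$mol_id == res$mol_id[g] &
                  res$res_local == res$res_local[g] - 1L)
    if (length(cand)) prv[g] <- cand
  }
  HB <- function(d, a) {
    ifelse(is.na(d) | is.na(a), FALSE, hb[cbind(pmax(d, 1), pmax(a, 1))] &
             !is.na(d) & !is.na(a))
  }

  label <- rep("other", nr)
  partner <- rep(NA_integer_, nr)
  anti <- matrix(FALSE, nr, nr); para <- matrix(FALSE, nr, nr)
  # bridge patterns over residue pairs with any hbond relation nearby
  cand_pairs <- which(hb | t(hb), arr.ind = TRUE)
  if (nrow(cand_pairs)) {
    ij <- unique(rbind(cand_pairs,
                       cbind(prv[cand_pairs[, 1]], nxt[cand_pairs[, 2]]),
                       cbind(nxt[cand_pairs[, 1]], prv[cand_pairs[, 2]])))
    ij <- ij[!is.na(ij[, 1]) & !is.na(ij[, 2]), , drop = FALSE]
    for (q in seq_len(nrow(ij))) {
      i <- ij[q, 1]; j <- ij[q, 2]
      if (i >= j) next
      sep_ok <- res$mol_id[i] != res$mol_id[j] ||
        abs(res$res_local[i] - res$res_local[j]) > 2
      if (!sep_ok) next
      if ((HB(j, i) && HB(i, j)) ||
          (HB(nxt[j], prv[i]) && HB(nxt[i], prv[j])))
        anti[i, j] <- anti[j, i] <- TRUE
      if ((HB(j, prv[i]) && HB(nxt[i], j)) ||
          (HB(i, prv[j]) && HB(nxt[j], i)))
        para[i, j] <- para[j, i] <- TRUE
    }
  }

  # helix: >= 2 consecutive n-turns
  is_helix <- rep(FALSE, nr)
  turn <- function(n) {
    # turn_at[i] TRUE when CO(i) accepts from NH(i+n) on the same chain
    t_at <- rep(FALSE, nr)
    for (i in seq_len(nr)) {
      j <- i
      ok <- TRUE
      for (s in seq_len(n)) { j <- nxt[j]; if (is.na(j)) { ok <- FALSE; break } }
      if (ok && hb[j, i]) t_at[i] <- TRUE
    }
    t_at
  }
  for (n in 3:5) {
    t_at <- turn(n)
    for (i in seq_len(nr)) {
      if (t_at[i] && !is.na(nxt[i]) && t_at[nxt[i]]) {
        j <- i
        for (s in seq_len(n)) { j <- nxt[j]; if (is.na(j)) break
          is_helix[j] <- TRUE }
      }
    }
  }

  for (i in seq_len(nr)) {
    ap <- which(anti[i, ]); pp <- which(para[i, ])
    if (length(ap)) {
      inter <- any(res$mol_id[ap] != res$mol_id[i])
      label[i] <- if (inter) "beta_anti_inter" else "beta_anti_intra"
      partner[i] <- ap[1]
    } else if (length(pp)) {
      label[i] <- "beta_para"
      partner[i] <- pp[1]
    } else if (is_helix[i]) {
      label[i] <- "helix"
    }
  }
  res$label <- label
  res$partner <- partner
  list(labels = res[res$amino, c("gid", "mol_id", "res_local", "label",
                                 "partner")],
       hbonds = hbl)
}

#' Secondary-structure fractions along a trajectory
#'
#' Per frame: the fraction of amino-acid residues in intermolecular
#' antiparallel beta-sheet, in helix (alpha, 3-10 or pi), in
#' intramolecular antiparallel beta and in parallel beta.
#'
#' @param traj `fp_trajectory` (or fixture trajectory).
#' @param system `fp_system`.
#' @param stride Analyse every `stride`-th frame.
#' @return data.frame with `time` (ps) and the four fractions.
#' @export
ss_ratio_series <- function(traj, system, stride = 1) {
  idx <- seq(1, n_frames(traj), by = stride)
  out <- lapply(idx, function(i) {
    ss <- assign_ss(frame_coords(traj, i), system, box = traj$box)
    lb <- ss$labels$label
    data.frame(time = traj$times[i],
               beta_inter = mean(lb == "beta_anti_inter"),
               helix = mean(lb == "helix"),
               beta_intra = mean(lb == "beta_anti_intra"),
               beta_para = mean(lb == "beta_para"))
  })
  do.call(rbind, out)
}

#' Average secondary-structure series over replicas
#'
#' @param series_list List of data.frames from [ss_ratio_series()] with
#'   identical time grids.
#' @return data.frame of the same shape with fractions averaged.
#' @export
average_over_replicas <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  t0 <- series_list[[1]]$time
  for (s in series_list)
    if (!isTRUE(all.equal(s$time, t0)))
      stop("replica series have different time grids")
  out <- series_list[[1]]
  for (cc in setdiff(names(out), "time"))
    out[[cc]] <- rowMeans(sapply(series_list, function(s) s[[cc]]))
  out
}
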