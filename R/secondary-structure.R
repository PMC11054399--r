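## Kabsch-Sander secondary-structure assignment (H/E/T/C subset).
##
## Backbone hydrogen bonds are scored with the electrostatic energy
## E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, with
## the amide hydrogen reconstructed 1 A from N along the previous
## residue's C=O direction; a bond exists when E < -0.5 kcal/mol.
## Helices are runs of consecutive i -> i+4 bonds, strands come from the
## parallel/antiparallel bridge rules, turns from i -> i+3 bonds outside
## helices; everything else is coil.

.KS_Q <- 0.084 * 332
.KS_HBOND_CUTOFF <- -0.5

# per-chain backbone table: rows = residues, coordinates of N, CA, C, O
.backbone_table <- function(traj, sel, frame) {
  a <- traj$atoms[sel, , drop = FALSE]
  xyz <- .frame_xyz(traj, sel, frame)
  key <- paste(a$chain, a$resid, sep = ":")
  res_keys <- unique(key)
  out <- list()
  for (rk in res_keys) {
    rows <- which(key == rk)
    nm <- a$name[rows]
    need <- c("N", "CA", "C", "O")
    if (!all(need %in% nm)) {
      out[[rk]] <- list(ok = FALSE, chain = a$chain[rows[1]],
                        resid = a$resid[rows[1]])
      next
    }
    get <- function(at) xyz[rows[match(at, nm)], ]
    out[[rk]] <- list(ok = TRUE, chain = a$chain[rows[1]],
                      resid = a$resid[rows[1]],
                      N = get("N"), CA = get("CA"), C = get("C"),
                      O = get("O"))
  }
  out
}

# Kabsch-Sander H-bond energy, CO of acceptor `acc`, NH of donor `don`;
# H reconstructed from the donor's preceding residue (NULL for chain start)
.ks_energy <- function(acc, don, don_prev) {
  if (is.null(don_prev)) return(0)
  co <- don_prev$C - don_prev$O
  H <- don$N + co / sqrt(sum(co^2))
  r_ON <- sqrt(sum((acc$O - don$N)^2))
  r_CH <- sqrt(sum((acc$C - H)^2))
  r_OH <- sqrt(sum((acc$O - H)^2))
  r_CN <- sqrt(sum((acc$C - don$N)^2))
  if (min(r_ON, r_CH, r_OH, r_CN) < 0.5) return(-9.9)  # clash convention
  .KS_Q * (1 / r_ON + 1 / r_CH - 1 / r_OH - 1 / r_CN)
}

#' Assign secondary structure (Kabsch-Sander H/E/T/C subset)
#'
#' Computes backbone hydrogen bonds from the Kabsch-Sander energy and
#' assigns: H (alpha-helix) to residues covered by two consecutive
#' i -> i+4 bonds; E (strand) to residues in parallel or antiparallel
#' bridges; T (turn) to residues covered by an i -> i+3 bond not already
#' helical; C otherwise. Residues with missing backbone atoms are
#' labelled C with a warning.
#'
#' @param traj \code{\link{trajectory}}.
#' @param sel Atom selection restricting the chains considered
#'   (default all atoms).
#' @param frame Frame index (default 1).
#' @return List of class \code{"ss_result"}: \code{assignment} data.frame
#'   (chain, resid, ss), \code{fractions} named vector over H/E/T/C.
#' @export
assign_secondary_structure <- function(traj, sel = NULL, frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_sel(traj, sel)
  bb <- .backbone_table(traj, sel, frame)
  n <- length(bb)
  chains <- vapply(bb, `[[`, "", "chain")
  ok <- vapply(bb, `[[`, TRUE, "ok")
  if (any(!ok))
    warning(sum(!ok), " residue(s) with missing backbone atoms labelled C")
  # residue i's predecessor within its chain (positional)
  prev_idx <- c(NA_integer_, seq_len(n - 1L))
  prev_idx[c(TRUE, chains[-1] != chains[-n])] <- NA_integer_

  # hb[i, j]: CO of residue i accepts the NH of residue j
  hb <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    if (!ok[j] || is.na(prev_idx[j]) || !ok[prev_idx[j]]) next
    for (i in seq_len(n)) {
      if (!ok[i] || i == j || abs(i - j) == 1L && chains[i] == chains[j])
        next
      if (.ks_energy(bb[[i]], bb[[j]], bb[[prev_idx[j]]]) <
          .KS_HBOND_CUTOFF)
        hb[i, j] <- TRUE
    }
  }
  same_chain_run <- function(i, k)  # i..i+k all one chain, in range
    i + k <= n && all(chains[i:(i + k)] == chains[i])

  ss <- rep("C", n)
  # helix: two consecutive i -> i+4 turns cover residues i+1 .. i+4
  turn4 <- vapply(seq_len(n), function(i)
    same_chain_run(i, 4L) && hb[i, i + 4L], logical(1))
  for (i in seq_len(n - 1L))
    if (turn4[i] && turn4[i + 1L])
      ss[(i + 1L):(i + 4L)] <- "H"
  # strand: bridge rules (distinct chains or |i-j| >= 3)
  hb_at <- function(i, j) !is.na(i) && !is.na(j) && hb[i, j]
  bridge <- function(i, j) {
    ip <- prev_idx[i]; jp <- prev_idx[j]
    inx <- if (same_chain_run(i, 1L)) i + 1L else NA_integer_
    jnx <- if (same_chain_run(j, 1L)) j + 1L else NA_integer_
    par <- (hb_at(ip, j) && hb_at(j, inx)) ||
      (hb_at(jp, i) && hb_at(i, jnx))
    anti <- (hb[i, j] && hb[j, i]) || (hb_at(ip, jnx) && hb_at(jp, inx))
    par || anti
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (chains[i] == chains[j] && abs(i - j) < 3L) next
    if (bridge(i, j)) {
      if (ss[i] == "C" || ss[i] == "T") ss[i] <- "E"
      if (ss[j] == "C" || ss[j] == "T") ss[j] <- "E"
    }
  }
  # turn: i -> i+3 bond, residues not already assigned
  for (i in seq_len(n))
    if (same_chain_run(i, 3L) && hb[i, i + 3L])
      for (k in (i + 1L):(i + 2L)) if (ss[k] == "C") ss[k] <- "T"
  ss[!ok] <- "C"  # incomplete backbone is never assigned structure
  assignment <- data.frame(
    chain = chains,
    resid = vapply(bb, `[[`, 0L, "resid"),
    ss = ss, stringsAsFactors = FALSE, row.names = NULL)
  fractions <- vapply(c(H = "H", E = "E", T = "T", C = "C"),
                      function(s) mean(ss == s), numeric(1))
  structure(list(assignment = assignment, fractions = fractions),
            class = "ss_result")
}

#' @export
print.ss_result <- function(x, ...) {
  cat("secondary structure fractions:\n")
  print(round(100 * x$fractions, 1))
  invisible(x)
}
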