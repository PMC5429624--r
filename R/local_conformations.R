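# Local-conformation alphabets: protein blocks (PLC, 16 letters a-p, Z
# placeholder) from backbone dihedrals, and the 12-class RNA local-conformation
# alphabet (RLC, a-l) from secondary structure.

# circular angular difference in degrees, in [0, 180]
.circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Assign protein-block letters from backbone dihedrals
#'
#' Each position is labelled with the protein-block prototype minimising the
#' angular RMSD (RMSDA, circular differences) between its eight reference
#' dihedrals and the eight observed dihedrals of the 5-residue window centred
#' on the position: psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1),
#' psi(i+1), phi(i+2). Positions whose window extends past the chain or
#' contains an undefined dihedral get the placeholder `Z`. Ties are broken
#' towards the alphabetically first letter.
#'
#' @param x An [rpi_complex()] (dihedrals must be computed) or a numeric vector
#'   of phi angles.
#' @param psi Numeric vector of psi angles (same length as `x`) when `x` is a
#'   phi vector.
#' @param prototypes Prototype dihedral matrix; defaults to [plc_prototypes()].
#' @return A character scalar over `{a..p, Z}`, one letter per residue.
#' @export
assign_plc <- function(x, psi = NULL, prototypes = plc_prototypes()) {
  if (inherits(x, "rpi_complex")) {
    phi <- x$protein$phi
    psi <- x$protein$psi
  } else {
    phi <- as.numeric(x)
    psi <- as.numeric(psi)
    stopifnot(length(phi) == length(psi))
  }
  n <- length(phi)
  out <- rep("Z", n)
  if (n >= 5) {
    for (i in 3:(n - 2)) {
      w <- c(psi[i - 2], phi[i - 1], psi[i - 1], phi[i],
             psi[i], phi[i + 1], psi[i + 1], phi[i + 2])
      if (anyNA(w)) next
      rmsda <- sqrt(rowMeans(.circ_diff(prototypes,
                                        matrix(w, nrow(prototypes), 8,
                                               byrow = TRUE))^2))
      out[i] <- rownames(prototypes)[which.min(rmsda)]
    }
  }
  paste(out, collapse = "")
}

# Dot-bracket parsing ----------------------------------------------------------

#' Parse a dot-bracket string into a pair table
#'
#' @param db Dot-bracket string over `".()"` (pseudoknot symbols rejected).
#' @return Integer vector `pt` with `pt[i] = j` if i pairs with j, 0 if
#'   unpaired.
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (length(ch) && !all(ch %in% c(".", "(", ")")))
    stop("dot-bracket may only contain '.', '(' and ')' (pseudoknots not supported)")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '(' at ", stack[1])
  pt
}

# Loop decomposition of a nested pair table. Returns a list of loops, each
# with: closing pair (0,0 for the exterior loop), branch pairs (k, l), and the
# unpaired runs between consecutive elements.
.decompose_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  scan_loop <- function(i, j) {
    # scan the loop enclosed by pair (i, j); (0, n+1) = exterior
    branches <- matrix(integer(0), ncol = 2)
    runs <- list()
    cur <- integer(0)
    k <- i + 1L
    while (k <= j - 1L) {
      if (pt[k] == 0L) {
        cur <- c(cur, k)
        k <- k + 1L
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- integer(0)
        branches <- rbind(branches, c(k, pt[k]))
        k <- pt[k] + 1L
      }
    }
    runs[[length(runs) + 1L]] <- cur
    loops[[length(loops) + 1L]] <<- list(closing = c(i, j),
                                         branches = branches, runs = runs)
    for (b in seq_len(nrow(branches)))
      scan_loop(branches[b, 1], branches[b, 2])
  }
  scan_loop(0L, n + 1L)
  loops
}

#' Assign RNA local-conformation letters from a dot-bracket string
#'
#' The 12 classes: `a` hairpin loop, `b` stem, `c` stem branch (junction-facing
#' pair of a helix entering a multiloop), `d`/`h` left/right internal loop,
#' `e`/`i` left/right bulge, `f`/`j` and `g`/`k` the corresponding
#' internal-loop/bulge variants inside a multiloop junction, `l` unknown
#' (unpaired external). See the methods vignette for the junction conventions.
#'
#' @param db Dot-bracket string (balanced, over `".()"`).
#' @return A character scalar over `{a..l}`, one letter per nucleotide.
#' @export
assign_rlc <- function(db) {
  pt <- parse_dot_bracket(db)
  n <- length(pt)
  if (n == 0) return("")
  out <- ifelse(pt > 0, "b", "l")
  for (loop in .decompose_loops(pt)) {
    nb <- nrow(loop$branches)
    runs <- loop$runs
    exterior <- loop$closing[1] == 0L
    if (exterior) next  # unpaired external stays 'l', helix ends stay 'b'
    if (nb == 0L) {
      # hairpin
      out[runs[[1]]] <- "a"
    } else if (nb == 1L) {
      r5 <- runs[[1]]; r3 <- runs[[2]]
      if (length(r5) && length(r3)) {       # internal loop
        out[r5] <- "d"; out[r3] <- "h"
      } else if (length(r5)) {              # 5' bulge
        out[r5] <- "e"
      } else if (length(r3)) {              # 3' bulge
        out[r3] <- "i"
      }
    } else {
      # multiloop junction: junction-facing pair of every entering helix -> c
      out[loop$closing] <- "c"
      out[as.vector(loop$branches)] <- "c"
      # unpaired runs: those preceding a branch helix take the 5' (left)
      # variants, the run after the last branch the 3' (right) variants;
      # single-nucleotide runs are bulge-like, longer runs internal-loop-like
      for (r in seq_along(runs)) {
        run <- runs[[r]]
        if (!length(run)) next
        left <- r <= nb
        out[run] <- if (length(run) == 1L) {
          if (left) "g" else "k"
        } else {
          if (left) "f" else "j"
        }
      }
    }
  }
  paste(out, collapse = "")
}

#' Assign RNA local conformations from an explicit base-pair list
#'
#' Equivalent to [assign_rlc()] on the corresponding dot-bracket string;
#' crossing (pseudoknotted) pairs are rejected.
#'
#' @param pairs Two-column matrix or data frame of 1-based pairs (i, j), i < j.
#' @param length Number of nucleotides.
#' @return A character scalar over `{a..l}`.
#' @export
rlc_from_pairs <- function(pairs, length) {
  pairs <- as.matrix(pairs)
  db <- rep(".", length)
  if (nrow(pairs)) {
    storage.mode(pairs) <- "integer"
    if (any(pairs[, 1] >= pairs[, 2]) || any(pairs < 1) || any(pairs > length))
      stop("pairs must satisfy 1 <= i < j <= length")
    if (anyDuplicated(as.vector(pairs)))
      stop("a position may appear in at most one pair")
    for (a in seq_len(nrow(pairs))) for (b in seq_len(nrow(pairs))) {
      i <- pairs[a, 1]; j <- pairs[a, 2]; k <- pairs[b, 1]; l <- pairs[b, 2]
      if (i < k && k < j && j < l)
        stop("crossing base pairs (pseudoknot) not supported: (",
             i, ",", j, ") x (", k, ",", l, ")")
    }
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  assign_rlc(paste(db, collapse = ""))
}
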