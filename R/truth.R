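#' Planted cleavage truth model
#'
#' A generative model of per-target cleavage probability used by the
#' simulator and by parameter-recovery tests. The probability that a
#' molecule with mismatch set M is cleaved is multiplicative:
#'
#' `p(target) = on_target_prob * prod_{p in M} position_weights[p] *
#'              prod_{p in M} base_penalties[obs_base, p] *
#'              prod_{(p,q) in MxM} epistasis[p, q]`
#'
#' with all probabilities clamped to `[0, 1]`. Position indices are
#' PAM-proximal (position 1 next to the PAM), so a seed-region penalty is a
#' low weight at small indices.
#'
#' For pull-down experiments, supply `binding` and `pcut` components (each a
#' `list(on = <prob>, position_weights = <vector>)`); the overall cleavage
#' probability then factorizes as `binding * pcut` per encounter and the
#' top-level `on_target_prob`/`position_weights` are ignored.
#'
#' @param guide a [guide_spec()].
#' @param on_target_prob cleavage probability of the perfect-match target.
#' @param position_weights length-`L` multiplicative penalties in `[0, 1]`,
#'   applied once per mismatched position; defaults to a PAM-proximity
#'   gradient ([seed_gradient_weights()]).
#' @param base_penalties optional 4 x L matrix (rows A,C,G,T) of multipliers
#'   for the observed target base at a mismatched position.
#' @param epistasis optional L x L symmetric matrix of pair multipliers
#'   (upper triangle used), applied once per mismatched position pair.
#' @param binding,pcut optional binding / cleavage-given-binding components,
#'   each `list(on =, position_weights =, base_penalties =, epistasis =)`
#'   (the last two optional).
#' @return an object of class `blt_truth`.
#' @seealso [truth_cut_prob()], [truth_binding_prob()], [truth_pcut_prob()]
#' @export
cleavage_truth <- function(guide, on_target_prob = 0.9,
                           position_weights = NULL,
                           base_penalties = NULL, epistasis = NULL,
                           binding = NULL, pcut = NULL) {
  stopifnot(inherits(guide, "blt_guide"))
  L <- guide$length
  if (is.null(position_weights)) position_weights <- seed_gradient_weights(L)
  .check_weights <- function(w, what) {
    if (length(w) != L || any(w < 0) || any(w > 1))
      stop(what, " must be ", L, " probabilities in [0,1]", call. = FALSE)
    w
  }
  position_weights <- .check_weights(position_weights, "position_weights")
  if (!is.null(base_penalties)) {
    stopifnot(is.matrix(base_penalties), nrow(base_penalties) == 4L,
              ncol(base_penalties) == L)
    rownames(base_penalties) <- DNA_BASES
  }
  if (!is.null(epistasis))
    stopifnot(is.matrix(epistasis), nrow(epistasis) == L, ncol(epistasis) == L)
  norm_channel <- function(ch, what) {
    if (is.null(ch)) return(NULL)
    stopifnot(is.list(ch), !is.null(ch$on))
    if (is.null(ch$position_weights)) ch$position_weights <- rep(1, L)
    ch$position_weights <- .check_weights(ch$position_weights,
                                          paste0(what, "$position_weights"))
    ch
  }
  structure(
    list(guide = guide, on_target_prob = on_target_prob,
         position_weights = position_weights,
         base_penalties = base_penalties, epistasis = epistasis,
         binding = norm_channel(binding, "binding"),
         pcut = norm_channel(pcut, "pcut")),
    class = "blt_truth")
}

#' PAM-proximity (seed) position-weight gradient
#'
#' Mismatch penalty profile in which PAM-proximal (seed) mismatches are
#' strongly deleterious and PAM-distal mismatches are well tolerated:
#' the weight rises linearly from `w_seed` at position 1 to `w_distal` at
#' position `L`.
#'
#' @param L spacer length.
#' @param w_seed multiplier for a mismatch adjacent to the PAM.
#' @param w_distal multiplier for the most PAM-distal mismatch.
#' @return numeric vector of length `L`.
#' @export
seed_gradient_weights <- function(L, w_seed = 0.05, w_distal = 0.95) {
  w_seed + (w_distal - w_seed) * (seq_len(L) - 1) / (L - 1)
}

## multiplicative per-target probability for one channel
.channel_prob <- function(on, pw, bp, ep, mm, n) {
  lp <- rep(log(on), n)
  if (nrow(mm)) {
    lw <- log(pw)
    f <- mm[, .(d = sum(lw[pos])), by = idx]
    if (!is.null(bp)) {
      fb <- mm[, .(d = sum(log(bp[cbind(obs, pos)]))), by = idx]
      f <- merge(f, fb, by = "idx", suffixes = c("", ".b"))
      f[, d := d + d.b][, d.b := NULL]
    }
    if (!is.null(ep)) {
      fe <- mm[, .(d = {
        if (.N < 2L) 0 else {
          cp <- utils::combn(pos, 2L)
          sum(log(ep[cbind(pmin(cp[1, ], cp[2, ]), pmax(cp[1, ], cp[2, ]))]))
        }
      }), by = idx]
      f <- merge(f, fe, by = "idx", suffixes = c("", ".e"))
      f[, d := d + d.e][, d.e := NULL]
    }
    lp[f$idx] <- lp[f$idx] + f$d
  }
  pmin(pmax(exp(lp), 0), 1)
}

#' Per-target truth probabilities
#'
#' `truth_cut_prob()` returns the planted overall cleavage probability for
#' each target (equal to `binding * pcut` when those channels are defined);
#' `truth_binding_prob()` and `truth_pcut_prob()` return the channel
#' probabilities (1 / the overall probability respectively when no channel
#' is defined).
#'
#' @param truth a [cleavage_truth()] model.
#' @param targets character vector of target sequences.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
truth_cut_prob <- function(truth, targets) {
  stopifnot(inherits(truth, "blt_truth"))
  if (!is.null(truth$binding) || !is.null(truth$pcut))
    return(truth_binding_prob(truth, targets) *
             truth_pcut_prob(truth, targets))
  mm <- mismatch_table(targets, truth$guide)
  .channel_prob(truth$on_target_prob, truth$position_weights,
                truth$base_penalties, truth$epistasis, mm, length(targets))
}

#' @rdname truth_cut_prob
#' @export
truth_binding_prob <- function(truth, targets) {
  stopifnot(inherits(truth, "blt_truth"))
  if (is.null(truth$binding)) return(rep(1, length(targets)))
  mm <- mismatch_table(targets, truth$guide)
  .channel_prob(truth$binding$on, truth$binding$position_weights,
                truth$binding$base_penalties, truth$binding$epistasis,
                mm, length(targets))
}

#' @rdname truth_cut_prob
#' @export
truth_pcut_prob <- function(truth, targets) {
  stopifnot(inherits(truth, "blt_truth"))
  if (is.null(truth$pcut)) return(truth_cut_prob(truth, targets))
  mm <- mismatch_table(targets, truth$guide)
  .channel_prob(truth$pcut$on, truth$pcut$position_weights,
                truth$pcut$base_penalties, truth$pcut$epistasis,
                mm, length(targets))
}
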