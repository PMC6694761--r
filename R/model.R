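#' Binary mismatch encoding
#'
#' Encodes guide:target mismatches as a binary 4 x L matrix — rows are the
#' observed **target** base A, C, G, T; columns are positions 1..L
#' (PAM-proximal first) — with a 1 wherever the target base differs from
#' the spacer base, and 0 elsewhere. The flat form is the row-major
#' concatenation (row A positions 1..L, then C, G, T), giving a 1 x 4L
#' binary vector (84 entries for a 21-nt guide). Column sums are at most 1
#' and the total equals the Hamming distance to the spacer; the all-zero
#' vector is the perfect match.
#'
#' `encode_mismatches()` encodes many targets into an n x 4L matrix;
#' `encode_matrix()` returns the 4 x L matrix of a single target.
#'
#' @param targets character vector of target sequences (spacer length,
#'   A/C/G/T only; ambiguous bases are an error).
#' @param guide a [guide_spec()].
#' @return `encode_mismatches()`: integer matrix n x 4L with attributes
#'   `L` and `convention` (`"target-base"`); `encode_matrix()`: 4 x L
#'   integer matrix with rownames A, C, G, T.
#' @export
encode_mismatches <- function(targets, guide) {
  L <- guide$length
  mm <- mismatch_table(targets, guide)
  enc <- matrix(0L, nrow = length(targets), ncol = 4L * L)
  if (nrow(mm)) {
    col <- (match(mm$obs, DNA_BASES) - 1L) * L + mm$pos
    enc[cbind(mm$idx, col)] <- 1L
  }
  colnames(enc) <- paste0(rep(DNA_BASES, each = L), rep(seq_len(L), 4L))
  attr(enc, "L") <- L
  attr(enc, "convention") <- "target-base"
  enc
}

#' @rdname encode_mismatches
#' @param target a single target sequence.
#' @export
encode_matrix <- function(target, guide) {
  flat <- encode_mismatches(target, guide)
  matrix(flat[1L, ], nrow = 4L, byrow = TRUE,
         dimnames = list(DNA_BASES, seq_len(guide$length)))
}

## forward pass of a single-hidden-layer nnet (sigmoid hidden, linear out)
## wts laid out as nnet does: per hidden unit (bias, inputs), then output
## (bias, hidden)
.nn_forward <- function(wts, n_in, size, x) {
  w1 <- matrix(wts[seq_len((n_in + 1L) * size)], nrow = n_in + 1L)
  w2 <- wts[(n_in + 1L) * size + seq_len(size + 1L)]
  h <- 1 / (1 + exp(-(cbind(1, x) %*% w1)))
  drop(cbind(1, h) %*% w2)
}

.r_squared <- function(obs, pred) {
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) return(NA_real_)
  cor(obs, pred)^2
}

#' Train a guide-specific cleavage model
#'
#' Fits a single-hidden-layer neural-network regression from flat binary
#' mismatch encodings to normalized cleavage efficiency. Data are split
#' into training / validation / test fractions; a small grid of weight
#' decays and iteration budgets is fit on the training split with a
#' full-batch quasi-Newton optimizer (BFGS, via [nnet::nnet()]), the
#' candidate with the best validation R^2 is kept, and its performance on
#' the untouched test split is reported. A fixed seed makes the split,
#' the initial weights and hence the fit reproducible.
#'
#' @param targets target sequences, or a pre-computed encoding matrix from
#'   [encode_mismatches()].
#' @param eta numeric response (normalized cleavage efficiencies).
#' @param guide a [guide_spec()] (required when `targets` are sequences).
#' @param split fractions (train, validation, test); must sum to 1.
#' @param hidden hidden-layer width (10 by default).
#' @param seed integer seed controlling split and initialization.
#' @param maxit_grid,decay_grid candidate iteration budgets / weight
#'   decays; all combinations are tried and validation-selected.
#' @param min_rows minimum number of rows required to train.
#' @return an object of class `blt_model`: weights and architecture plus
#'   training metadata (`r2_train`, `r2_val`, `r2_test`, `split`, `seed`,
#'   `optimizer`, chosen `maxit`/`decay`, encoding `convention`).
#' @export
train_guide_model <- function(targets, eta, guide = NULL,
                              split = c(0.70, 0.15, 0.15),
                              hidden = 10L, seed = 1L,
                              maxit_grid = c(150L, 400L),
                              decay_grid = c(1e-4, 1e-2),
                              min_rows = 50L) {
  if (is.matrix(targets)) {
    x <- targets
    L <- attr(x, "L")
    if (is.null(L)) L <- ncol(x) / 4L
    gname <- if (!is.null(guide)) guide$name else "unknown"
  } else {
    stopifnot(inherits(guide, "blt_guide"))
    x <- encode_mismatches(targets, guide)
    L <- guide$length
    gname <- guide$name
  }
  stopifnot(length(eta) == nrow(x), all(is.finite(eta)))
  stopifnot(abs(sum(split) - 1) < 1e-8, length(split) == 3L)
  n <- nrow(x)
  if (n < min_rows)
    stop("need at least ", min_rows, " rows to train (got ", n, ")",
         call. = FALSE)

  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- floor(split[1] * n)
  n_va <- floor(split[2] * n)
  i_tr <- perm[seq_len(n_tr)]
  i_va <- perm[n_tr + seq_len(n_va)]
  i_te <- perm[(n_tr + n_va + 1L):n]

  base <- list(guide = gname, L = L, n_in = ncol(x), hidden = hidden,
               split = split, seed = seed,
               convention = attr(x, "convention") %||% "target-base",
               optimizer = "BFGS (nnet)",
               n_train = length(i_tr), n_val = length(i_va),
               n_test = length(i_te))

  if (stats::sd(eta[i_tr]) == 0) {
    warning("constant response in training split; model returns the constant",
            call. = FALSE)
    out <- c(base, list(constant = eta[i_tr][1L], wts = NULL,
                        maxit = NA, decay = NA,
                        r2_train = NA_real_, r2_val = NA_real_,
                        r2_test = NA_real_))
    return(structure(out, class = "blt_model"))
  }

  cand <- CJ(maxit = maxit_grid, decay = decay_grid)
  best <- NULL
  for (ci in seq_len(nrow(cand))) {
    set.seed(seed + ci)                       # reproducible init per candidate
    fit <- nnet::nnet(x[i_tr, , drop = FALSE], eta[i_tr],
                      size = hidden, linout = TRUE, trace = FALSE,
                      maxit = cand$maxit[ci], decay = cand$decay[ci],
                      MaxNWts = 100000L)
    pv <- .nn_forward(fit$wts, ncol(x), hidden, x[i_va, , drop = FALSE])
    r2v <- .r_squared(eta[i_va], pv)
    if (is.null(best) || (!is.na(r2v) && r2v > best$r2_val)) {
      best <- list(wts = fit$wts, maxit = cand$maxit[ci],
                   decay = cand$decay[ci], r2_val = r2v)
    }
  }
  pt <- .nn_forward(best$wts, ncol(x), hidden, x[i_tr, , drop = FALSE])
  pe <- .nn_forward(best$wts, ncol(x), hidden, x[i_te, , drop = FALSE])
  out <- c(base, list(constant = NULL, wts = best$wts,
                      maxit = best$maxit, decay = best$decay,
                      r2_train = .r_squared(eta[i_tr], pt),
                      r2_val = best$r2_val,
                      r2_test = .r_squared(eta[i_te], pe)))
  structure(out, class = "blt_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.blt_model <- function(x, ...) {
  cat(sprintf(
    "<blt_model> guide %s | %d -> %d -> 1 | %s\n", x$guide, x$n_in,
    x$hidden, x$optimizer))
  if (!is.null(x$constant)) {
    cat(sprintf("  degenerate: constant response %.4f\n", x$constant))
  } else {
    cat(sprintf("  R2 train %.3f | val %.3f | test %.3f (maxit %d, decay %g)\n",
                x$r2_train, x$r2_val, x$r2_test, x$maxit, x$decay))
  }
  invisible(x)
}

#' Predict normalized efficiency
#'
#' Applies a trained guide model to target sequences or to a pre-computed
#' encoding matrix. Predictions are raw network outputs (no clipping).
#'
#' @param model a [train_guide_model()] fit.
#' @param targets target sequences or an encoding matrix.
#' @param guide a [guide_spec()] (needed for sequences).
#' @return numeric vector of predicted eta.
#' @export
predict_eta <- function(model, targets, guide = NULL) {
  stopifnot(inherits(model, "blt_model"))
  x <- if (is.matrix(targets)) targets else {
    stopifnot(inherits(guide, "blt_guide"))
    encode_mismatches(targets, guide)
  }
  if (ncol(x) != model$n_in)
    stop("encoding width ", ncol(x), " does not match model input width ",
         model$n_in, call. = FALSE)
  if (!is.null(model$constant)) return(rep(model$constant, nrow(x)))
  .nn_forward(model$wts, model$n_in, model$hidden, x)
}

#' Cross-guide model transfer
#'
#' Evaluates a model trained on one guide against the measured
#' efficiencies of another guide's library: R^2 (squared Pearson) of the
#' model's predictions on the foreign data. Guide-specific models show a
#' much lower cross-guide than same-guide R^2.
#'
#' @param model a [train_guide_model()] fit for guide A.
#' @param targets,eta target sequences (or encoding matrix) and measured
#'   efficiencies for guide B.
#' @param guide [guide_spec()] of guide B (for sequence encoding; spacer
#'   lengths must match the model's input width).
#' @return list with `r_squared` and `n`.
#' @export
cross_guide_r2 <- function(model, targets, eta, guide = NULL) {
  pred <- predict_eta(model, targets, guide)
  list(r_squared = .r_squared(eta, pred), n = length(eta))
}

#' Serialize a guide model to portable JSON
#'
#' Weights plus all metadata needed to reproduce predictions; the loaded
#' model predicts through the package's own forward pass, so round-tripped
#' models give (numerically) identical output.
#'
#' @param model a `blt_model`.
#' @param path JSON file path.
#' @return `model_to_json()` the path (invisibly); `model_from_json()` the
#'   reconstructed `blt_model`.
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "blt_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$wts <- as.numeric(x$wts)
  x$split <- as.numeric(x$split)
  for (f in c("L", "n_in", "hidden", "seed", "maxit"))
    if (!is.null(x[[f]]) && !is.na(x[[f]])) x[[f]] <- as.integer(x[[f]])
  structure(x, class = "blt_model")
}
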