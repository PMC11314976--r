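#' Posture-specific spatial weight templates
#'
#' Returns the canonical 4 x 8 grids of per-channel coupling weights for the
#' respiratory and cardiac (BCG) signal sources under a given sleep posture.
#' Row index runs head-to-foot across the chest band (4 rows), column index
#' increases toward the subject's left (8 columns); channels are stored
#' row-major, so channel `c` sits at `row = (c-1) %/% 8 + 1`,
#' `col = (c-1) %% 8 + 1`.
#'
#' Template geometry encodes the static-moment argument for lateral postures:
#' the body tilts opposite to the offset of the centre of gravity, so the bulk
#' of the contact pressure (the weight centroid) lies on the opposite side of
#' the grid midline from the high-intensity contact peak. Supine contact is
#' broad and symmetric, with strictly more channels above half-maximum than
#' either lateral template. Both grids are normalized to maximum 1.
#'
#' @param posture One of `"supine"`, `"right_lateral"`, `"left_lateral"`.
#' @return A `spatial_template` object: list with `posture` and two 4 x 8
#'   matrices `resp_weights`, `bcg_weights` (max-normalized, non-negative).
#' @examples
#' tpl <- spatial_template("left_lateral")
#' range(tpl$resp_weights)
#' @export
spatial_template <- function(posture = posture_levels()) {
  posture <- match.arg(posture)
  g <- function(r0, c0, sr, sc, amp = 1) {
    r <- matrix(1:4, 4, 8)
    cc <- matrix(1:8, 4, 8, byrow = TRUE)
    amp * exp(-((r - r0)^2 / (2 * sr^2) + (cc - c0)^2 / (2 * sc^2)))
  }
  mirror <- function(m) m[, 8:1, drop = FALSE]
  norm1 <- function(m) m / max(m)
  left <- function() {
    # narrow contact peak on the subject's left (high columns), broad
    # weight lobe on the right of midline: centroid and argmax oppose
    resp <- norm1(g(2.5, 6.9, 0.9, 0.7) + g(2.5, 2.4, 1.5, 2.0, amp = 0.68))
    bcg  <- norm1(g(2.4, 6.2, 1.05, 1.2) + g(2.6, 2.9, 1.3, 1.7, amp = 0.45))
    list(resp = resp, bcg = bcg)
  }
  w <- switch(posture,
    supine = list(resp = norm1(g(2.5, 4.5, 1.3, 2.4)),
                  bcg  = norm1(g(2.5, 5.0, 1.4, 2.4))),
    left_lateral = left(),
    right_lateral = { l <- left(); list(resp = mirror(l$resp), bcg = mirror(l$bcg)) }
  )
  structure(list(posture = posture,
                 resp_weights = w$resp, bcg_weights = w$bcg),
            class = "spatial_template")
}

#' Summary geometry of a weight grid
#'
#' Column centroid, column of the maximum weight, and the number of cells at
#' or above half of the maximum, for one 4 x 8 weight grid. Used to check the
#' centroid/peak opposition property of lateral templates.
#'
#' @param w A 4 x 8 non-negative weight matrix.
#' @return A tibble with `centroid_col`, `argmax_col`, `n_above_half`.
#' @export
template_geometry <- function(w) {
  stopifnot(is.matrix(w), all(w >= 0))
  cols <- matrix(seq_len(ncol(w)), nrow(w), ncol(w), byrow = TRUE)
  peak <- which(w == max(w), arr.ind = TRUE)[1, ]
  tibble::tibble(
    centroid_col = sum(cols * w) / sum(w),
    argmax_col = unname(peak["col"]),
    n_above_half = sum(w >= max(w) / 2)
  )
}

# per-subject template variation: multiplicative lognormal cell jitter,
# renormalized to max 1 (draws from the ambient RNG stream)
perturb_template <- function(template, sdlog = 0.15) {
  jit <- function(m) {
    m <- m * exp(matrix(rnorm(length(m), 0, sdlog), nrow(m)))
    m / max(m)
  }
  template$resp_weights <- jit(template$resp_weights)
  template$bcg_weights <- jit(template$bcg_weights)
  template
}

# lateral body displacement: shift the whole contact pattern by `cols`
# columns toward the subject's left (positive) or right (negative); cells
# shifted in from the edge get a small residual contact weight
shift_template <- function(template, cols) {
  if (cols == 0) return(template)
  sh <- function(m) {
    out <- matrix(0.05 * max(m), nrow(m), ncol(m))
    if (cols > 0) out[, (1 + cols):8] <- m[, 1:(8 - cols)]
    else out[, 1:(8 + cols)] <- m[, (1 - cols):8]
    out / max(out)
  }
  template$resp_weights <- sh(template$resp_weights)
  template$bcg_weights <- sh(template$bcg_weights)
  template
}
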