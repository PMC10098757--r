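# Orthonormal Daubechies filter bank and periodized multilevel DWT.
#
# No wavelet package ships with this stack, so the pyramid algorithm is
# implemented here directly. The transform is periodized: with an orthonormal
# filter pair the analysis operator is orthogonal, so reconstruction is its
# adjoint, reconstruction of disjoint coefficient sets is exactly orthogonal,
# and coefficient energy equals reconstructed-signal energy to floating-point
# precision. Analysis length must be a multiple of 2^depth (callers truncate).

# Scaling (low-pass) decomposition filters for the extremal-phase Daubechies
# family, dbN = N vanishing moments, 2N taps. Standard published values.
.db_dec_lo <- list(
  db2 = c(-1.29409522551260370e-01, 2.24143868042013389e-01,
          8.36516303737807942e-01, 4.82962913144534156e-01),
  db3 = c(3.52262918857095333e-02, -8.54412738820266582e-02,
          -1.35011020010254584e-01, 4.59877502118491543e-01,
          8.06891509311092547e-01, 3.32670552950082632e-01),
  db4 = c(-1.05974017850690317e-02, 3.28830116668851966e-02,
          3.08413818355607640e-02, -1.87034811719093086e-01,
          -2.79837694168598543e-02, 6.30880767929858921e-01,
          7.14846570552915672e-01, 2.30377813308896506e-01),
  db5 = c(3.33572528547377125e-03, -1.25807519990819988e-02,
          -6.24149021279827437e-03, 7.75714938400457188e-02,
          -3.22448695846383748e-02, -2.42294887066382025e-01,
          1.38428145901320743e-01, 7.24308528437772936e-01,
          6.03829269797189649e-01, 1.60102397974192928e-01),
  db6 = c(-1.07730108530847959e-03, 4.77725751094551076e-03,
          5.53842201161496126e-04, -3.15820393174860298e-02,
          2.75228655303057269e-02, 9.75016055873230425e-02,
          -1.29766867567261940e-01, -2.26264693965439828e-01,
          3.15250351709197629e-01, 7.51133908021095364e-01,
          4.94623890398453059e-01, 1.11540743350109467e-01),
  db7 = c(3.53713799974520241e-04, -1.80164070404749085e-03,
          4.29577972921366515e-04, 1.25509985560998405e-02,
          -1.65745416306668815e-02, -3.80299369350144134e-02,
          8.06126091510830783e-02, 7.13092192668302594e-02,
          -2.24036184993874982e-01, -1.43906003928564979e-01,
          4.69782287405193122e-01, 7.29132090846235092e-01,
          3.96539319481917285e-01, 7.78520540850091841e-02),
  db8 = c(-1.17476784124769535e-04, 6.75449406450569331e-04,
          -3.91740373376947050e-04, -4.87035299345157414e-03,
          8.74609404740577662e-03, 1.39810279173982824e-02,
          -4.40882539307947546e-02, -1.73693010018075474e-02,
          1.28747426620478472e-01, 4.72484573913282795e-04,
          -2.84015542961546907e-01, -1.58291052563493059e-02,
          5.85354683654206731e-01, 6.75630736297289758e-01,
          3.12871590914299946e-01, 5.44158422431040081e-02),
  db9 = c(3.93473203162716026e-05, -2.51963188942710124e-04,
          2.30385763523195973e-04, 1.84764688305622655e-03,
          -4.28150368246343026e-03, -4.72320475775139716e-03,
          2.23616621236790956e-02, 2.50947114831451973e-04,
          -6.76328290613299743e-02, 3.07256814793333798e-02,
          1.48540749338106376e-01, -9.68407832229764565e-02,
          -2.93273783279174916e-01, 1.33197385825007564e-01,
          6.57288078051300517e-01, 6.04823123690111153e-01,
          2.43834674612590341e-01, 3.80779473638783450e-02),
  db10 = c(-1.32642028945212443e-05, 9.35886703200695919e-05,
           -1.16466855129285449e-04, -6.85856694959711619e-04,
           1.99240529518505613e-03, 1.39535174705290106e-03,
           -1.07331754833305745e-02, 3.60655356695616970e-03,
           3.32126740593410019e-02, -2.94575368218758134e-02,
           -7.13941471663970817e-02, 9.30573646035723484e-02,
           1.27369340335793252e-01, -1.95946274377377050e-01,
           -2.49846424327315381e-01, 2.81172343660577473e-01,
           6.88459039453603538e-01, 5.27201188931725628e-01,
           1.88176800077691497e-01, 2.66700579005555542e-02)
)

#' Daubechies analysis filter pair
#'
#' Returns the low-pass (scaling) and high-pass (wavelet) decomposition
#' filters for an orthogonal Daubechies wavelet. The high-pass filter is the
#' quadrature mirror of the low-pass one, so the periodized filter bank is
#' orthonormal.
#'
#' @param wavelet Wavelet name, one of `"db2"` through `"db10"`.
#' @return List with elements `lo` and `hi`, numeric filter taps.
#' @export
daubechies_filters <- function(wavelet = "db10") {
  lo <- .db_dec_lo[[wavelet]]
  if (is.null(lo)) {
    stop("unknown wavelet '", wavelet, "'; supported: ",
         paste(names(.db_dec_lo), collapse = ", "))
  }
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * rev(lo)
  list(lo = lo, hi = hi, name = wavelet, length = L)
}

# One periodized analysis step: stride-2 circular correlation with filter f.
.dwt_step <- function(x, f) {
  n <- length(x)
  k <- 0:(n / 2 - 1)
  a <- numeric(n / 2)
  for (m in seq_along(f)) {
    a <- a + f[m] * x[((2 * k + m - 1) %% n) + 1]
  }
  a
}

# Adjoint of the combined analysis step (exact inverse by orthonormality).
.idwt_step <- function(a, d, lo, hi) {
  n <- 2 * length(a)
  x <- numeric(n)
  k <- 0:(length(a) - 1)
  for (m in seq_along(lo)) {
    idx <- ((2 * k + m - 1) %% n) + 1
    x[idx] <- x[idx] + lo[m] * a + hi[m] * d
  }
  x
}

#' Multilevel periodized DWT
#'
#' Decomposes a signal to the requested depth. The input length must be a
#' multiple of `2^depth`.
#'
#' @param x Numeric vector.
#' @param depth Number of dyadic levels.
#' @param wavelet Daubechies wavelet name (see [daubechies_filters()]).
#' @return List with `approx` (deepest approximation coefficients) and
#'   `details` (list, level 1 = finest/highest frequency octave).
#' @export
dwt_periodic <- function(x, depth, wavelet = "db10") {
  if (length(x) %% 2^depth != 0) {
    stop("signal length must be a multiple of 2^depth = ", 2^depth)
  }
  flt <- daubechies_filters(wavelet)
  details <- vector("list", depth)
  a <- x
  for (j in seq_len(depth)) {
    details[[j]] <- .dwt_step(a, flt$hi)
    a <- .dwt_step(a, flt$lo)
  }
  structure(list(approx = a, details = details, depth = depth,
                 wavelet = wavelet, n = length(x)),
            class = "dwt_periodic")
}

#' Reconstruct one sub-band of a periodized DWT
#'
#' Inverts the transform with every coefficient set except the requested one
#' zeroed, yielding the time-domain contribution of that sub-band. Summing
#' the reconstructions of all `depth + 1` components returns the original
#' signal exactly, and their energies are exactly additive.
#'
#' @param dec A [dwt_periodic()] decomposition.
#' @param component `"approx"` or `"detail"`.
#' @param level Detail level (1 = finest); ignored for the approximation.
#' @return Numeric vector of the original length.
#' @export
dwt_reconstruct_component <- function(dec, component = c("approx", "detail"),
                                      level = NULL) {
  component <- match.arg(component)
  flt <- daubechies_filters(dec$wavelet)
  if (component == "approx") {
    a <- dec$approx
    start <- dec$depth
  } else {
    if (is.null(level) || level < 1 || level > dec$depth) {
      stop("detail level must be in 1..depth")
    }
    a <- .idwt_step(numeric(length(dec$details[[level]])),
                    dec$details[[level]], flt$lo, flt$hi)
    start <- level - 1
  }
  if (component == "approx") {
    # climb the full pyramid with zero details
    x <- a
    for (j in rev(seq_len(dec$depth))) {
      x <- .idwt_step(x, numeric(length(x)), flt$lo, flt$hi)
    }
    return(x)
  }
  x <- a
  if (start >= 1) {
    for (j in rev(seq_len(start))) {
      x <- .idwt_step(x, numeric(length(x)), flt$lo, flt$hi)
    }
  }
  x
}
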