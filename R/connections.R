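#' Connection set of one recurrent network
#'
#' Bundles the four weight matrices of a network — excitatory, inhibitory and
#' modulatory recurrent weights (`n_units x n_units`, entry `[k, l]` is the
#' strength from unit `k` to unit `l`) and the input weights
#' (`n_features x n_units`) — together with binary structural masks and the
#' global weight cap.  All weights are nonnegative, never exceed `max_weight`,
#' and are exactly zero wherever the corresponding mask is zero; these
#' invariants are preserved by [update_weights()].
#'
#' @param w_ex,w_inh,w_mod Square recurrent weight matrices.
#' @param w_inp Input weight matrix (`n_features x n_units`).
#' @param mask_ex,mask_inh,mask_mod,mask_inp Binary masks of the same shapes;
#'   default: 1 wherever the initial weight is nonzero.
#' @param max_weight Upper weight bound (default 4, the maximum weight
#'   permitted in the simulations).
#' @return An object of class `connection_set`.
#' @export
connection_set <- function(w_ex, w_inh, w_mod, w_inp,
                           mask_ex = NULL, mask_inh = NULL,
                           mask_mod = NULL, mask_inp = NULL,
                           max_weight = 4) {
  w_ex <- as.matrix(w_ex); w_inh <- as.matrix(w_inh)
  w_mod <- as.matrix(w_mod); w_inp <- as.matrix(w_inp)
  n <- nrow(w_ex)
  for (w in list(w_ex, w_inh, w_mod))
    if (!all(dim(w) == c(n, n))) stop("recurrent matrices must be n x n")
  if (ncol(w_inp) != n) stop("w_inp must have n_units columns")
  default_mask <- function(w) (w != 0) + 0
  conn <- structure(list(
    w_ex = w_ex, w_inh = w_inh, w_mod = w_mod, w_inp = w_inp,
    mask_ex = if (is.null(mask_ex)) default_mask(w_ex) else as.matrix(mask_ex),
    mask_inh = if (is.null(mask_inh)) default_mask(w_inh) else as.matrix(mask_inh),
    mask_mod = if (is.null(mask_mod)) default_mask(w_mod) else as.matrix(mask_mod),
    mask_inp = if (is.null(mask_inp)) default_mask(w_inp) else as.matrix(mask_inp),
    max_weight = max_weight, n_units = n, n_features = nrow(w_inp)),
    class = "connection_set")
  validate_connection_set(conn)
  conn
}

#' Validate the invariants of a connection set
#'
#' Checks nonnegativity, the `max_weight` cap, and that weights vanish
#' wherever their mask is zero.  Called on construction; exported so that
#' long-running simulations can re-assert the invariants.
#'
#' @param conn A [connection_set()].
#' @return `conn`, invisibly; signals an error on violation.
#' @export
validate_connection_set <- function(conn) {
  for (nm in c("ex", "inh", "mod", "inp")) {
    w <- conn[[paste0("w_", nm)]]
    m <- conn[[paste0("mask_", nm)]]
    if (!all(dim(w) == dim(m)))
      stop("mask_", nm, " shape does not match w_", nm)
    if (any(w < 0)) stop("negative weights in w_", nm)
    if (any(w > conn$max_weight + 1e-12))
      stop("weights above max_weight in w_", nm)
    if (any(w[m == 0] != 0)) stop("nonzero weight outside mask in w_", nm)
  }
  invisible(conn)
}

#' Aggregate synaptic inputs from presynaptic rates
#'
#' Computes the excitatory, inhibitory and modulatory input of every unit,
#' \deqn{I^{ex} = (W^{ex})^T g(p) + (W^{inp})^T I^{inp}, \quad
#'       I^{inh/mod} = (W^{inh/mod})^T g(p),}
#' i.e. the excitatory channel carries both recurrent and external drive while
#' inhibition and modulation are purely recurrent.
#'
#' @param conn A [connection_set()].
#' @param r Vector of presynaptic firing rates (length `n_units`).
#' @param i_inp External input feature vector (length `n_features`).
#' @return A list with components `i_ex`, `i_inh`, `i_mod` (each length
#'   `n_units`).
#' @examples
#' conn <- connection_set(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
#'                        matrix(c(1, 0), 1, 2))
#' compute_inputs(conn, r = c(0, 0), i_inp = 1)$i_ex
#' @export
compute_inputs <- function(conn, r, i_inp) {
  if (length(r) != conn$n_units)
    stop("rate vector length does not match the network size")
  if (length(i_inp) != conn$n_features)
    stop("input vector length does not match the number of input features")
  list(i_ex = drop(crossprod(conn$w_ex, r)) + drop(crossprod(conn$w_inp, i_inp)),
       i_inh = drop(crossprod(conn$w_inh, r)),
       i_mod = drop(crossprod(conn$w_mod, r)))
}
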