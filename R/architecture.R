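#' Architecture specification
#'
#' Sizes and initialization ranges of the hierarchical network.  Defaults are
#' the simulation values: 10 binary input features, a 200-unit sensory basis
#' network split evenly over two layers, and experts of 50 units each
#' (48 association units plus 2 motor units).  The extended variant has 3
#' experts; the monolithic variant has 1.
#'
#' @param n_input Number of external input features.
#' @param n_basis Sizes of the two basis-network layers.
#' @param n_assoc Association units per expert.
#' @param n_motor Motor units per expert.
#' @param n_experts Number of expert networks (>= 1).
#' @param max_weight Global weight cap.
#' @param init_general,init_motor,init_mod Uniform initialization ranges for
#'   generic connections, connections onto the motor layer, and modulatory
#'   connections.
#' @param fan_in Number of presynaptic partners per target unit within each
#'   recurrent connection block (random sparse sampling; `Inf` for all-to-all).
#'   Keeps the aggregate shunting drive of order one and preserves stimulus
#'   contrast through the hierarchy; see the methods vignette.
#' @param fan_input Number of input features sampled by each first-layer
#'   basis unit (`Inf` for all features); small values yield feature-selective
#'   first-layer units.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_input = 10, n_basis = c(100, 100),
                              n_assoc = 48, n_motor = 2, n_experts = 3,
                              max_weight = 4,
                              init_general = c(0, 0.2),
                              init_motor = c(0, 0.3),
                              init_mod = c(0, 0.1),
                              fan_in = 5, fan_input = 2) {
  if (length(n_basis) != 2 || any(n_basis < 1))
    stop("n_basis must give two positive layer sizes")
  if (n_experts < 1) stop("at least one expert network is required")
  if (any(c(n_input, n_assoc, n_motor) < 1)) stop("invalid layer sizes")
  if (fan_in < 1 || fan_input < 1) stop("fan-in values must be >= 1")
  structure(list(n_input = n_input, n_basis = n_basis, n_assoc = n_assoc,
                 n_motor = n_motor, n_experts = n_experts,
                 max_weight = max_weight, init_general = init_general,
                 init_motor = init_motor, init_mod = init_mod,
                 fan_in = fan_in, fan_input = fan_input),
            class = "architecture_spec")
}

#' Partition of units into layers
#'
#' @param spec An [architecture_spec()].
#' @return An object of class `network_layout` with index vectors `basis1`,
#'   `basis2`, per-expert lists `assoc` and `motor`, the per-expert union
#'   `experts`, and `n_units`.
#' @export
network_layout <- function(spec) {
  n1 <- spec$n_basis[1]; n2 <- spec$n_basis[2]
  basis1 <- seq_len(n1)
  basis2 <- n1 + seq_len(n2)
  offset <- n1 + n2
  per <- spec$n_assoc + spec$n_motor
  assoc <- motor <- experts <- vector("list", spec$n_experts)
  for (e in seq_len(spec$n_experts)) {
    base <- offset + (e - 1) * per
    assoc[[e]] <- base + seq_len(spec$n_assoc)
    motor[[e]] <- base + spec$n_assoc + seq_len(spec$n_motor)
    experts[[e]] <- c(assoc[[e]], motor[[e]])
  }
  structure(list(basis1 = basis1, basis2 = basis2, assoc = assoc,
                 motor = motor, experts = experts,
                 n_units = offset + spec$n_experts * per),
            class = "network_layout")
}

#' Build a network with the hierarchical connectivity restrictions
#'
#' Constructs the structural masks and draws the initial weights from the
#' architecture's uniform ranges, using R's current random stream.  The
#' allowed pathways are: input -> basis layer 1 (excitatory, via the input
#' matrix); basis layer 1 -> basis layer 2 feedforward excitation and
#' inhibition with modulatory feedback from layer 2 to layer 1; learned
#' lateral inhibition among the layer-2 units (their mutual competition);
#' basis layer 2 -> each expert's association layer (excitation/inhibition)
#' with modulatory feedback from the association layer back to basis layer 2;
#' and association -> motor excitation/inhibition within each expert.  There
#' are no connections between different experts.  Within an allowed block
#' each target unit samples `fan_in` random presynaptic partners (`fan_input`
#' input features for the first basis layer); lateral inhibition excludes
#' self-connections.
#'
#' Initial weights are uniform on `[0, 0.2]`, except connections onto the
#' motor layer (`[0, 0.3]`) and modulatory connections (`[0, 0.1]`).
#'
#' @param spec An [architecture_spec()].
#' @return A list with the [connection_set()] `conn` and the
#'   [network_layout()] `layout`.
#' @export
build_network <- function(spec) {
  layout <- network_layout(spec)
  n <- layout$n_units
  mask_ex <- mask_inh <- mask_mod <- matrix(0, n, n)
  mask_inp <- matrix(0, spec$n_input, n)

  # fill a block with `fan` random presynaptic partners per target column
  fill <- function(mask, rows, cols, fan) {
    fan <- min(fan, length(rows))
    for (l in cols)
      mask[if (length(rows) == fan) rows else sample(rows, fan), l] <- 1
    mask
  }
  fi <- spec$fan_in
  mask_inp <- fill(mask_inp, seq_len(spec$n_input), layout$basis1,
                   spec$fan_input)
  mask_ex <- fill(mask_ex, layout$basis1, layout$basis2, fi)
  mask_inh <- fill(mask_inh, layout$basis1, layout$basis2, fi)
  mask_mod <- fill(mask_mod, layout$basis2, layout$basis1, fi)
  # mutual competition in basis layer 2 (no self-inhibition)
  for (l in layout$basis2)
    mask_inh[sample(setdiff(layout$basis2, l), min(fi, length(layout$basis2) - 1)),
             l] <- 1
  for (e in seq_len(spec$n_experts)) {
    mask_ex <- fill(mask_ex, layout$basis2, layout$assoc[[e]], fi)
    mask_inh <- fill(mask_inh, layout$basis2, layout$assoc[[e]], fi)
    mask_ex <- fill(mask_ex, layout$assoc[[e]], layout$motor[[e]], fi)
    mask_inh <- fill(mask_inh, layout$assoc[[e]], layout$motor[[e]], fi)
  }
  # modulatory feedback onto basis layer 2 is sampled from the union of all
  # association layers, so the aggregate feedback drive on the basis network
  # does not grow with the number of experts (keeps the monolithic and
  # extended variants' sensory dynamics comparable)
  mask_mod <- fill(mask_mod, unlist(layout$assoc), layout$basis2, fi)

  motor_all <- unlist(layout$motor)
  draw <- function(mask, range, motor_range = NULL) {
    w <- matrix(0, nrow(mask), ncol(mask))
    idx <- mask == 1
    w[idx] <- runif(sum(idx), range[1], range[2])
    if (!is.null(motor_range)) {
      m <- mask
      m[, setdiff(seq_len(ncol(mask)), motor_all)] <- 0
      idx_m <- m == 1
      w[idx_m] <- runif(sum(idx_m), motor_range[1], motor_range[2])
    }
    w
  }
  w_ex <- draw(mask_ex, spec$init_general, spec$init_motor)
  w_inh <- draw(mask_inh, spec$init_general, spec$init_motor)
  w_mod <- draw(mask_mod, spec$init_mod)
  w_inp <- draw(mask_inp, spec$init_general)

  conn <- connection_set(w_ex, w_inh, w_mod, w_inp,
                         mask_ex, mask_inh, mask_mod, mask_inp,
                         max_weight = spec$max_weight)
  list(conn = conn, layout = layout)
}
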