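#' Connectivity specification
#'
#' Describes the four static distance-dependent synaptic weight matrices of
#' the one-dimensional excitatory-inhibitory network. Neurons of each
#' population are placed at normalized positions \eqn{x_k = k/N} on the unit
#' line \[0, 1); the synaptic kernel is the Gaussian pdf with standard
#' deviation `sigma_E` (excitatory projections) or `sigma_I` (inhibitory
#' projections) evaluated at the distance \eqn{|x_i - x_j|}. Each presynaptic
#' row is normalized to sum to one and scaled by the corresponding row budget
#' `W0_*`; inhibitory projections additionally carry a weak uniform component
#' `W_UI / N_target` on every entry.
#'
#' @param N_E,N_I population sizes.
#' @param sigma_E,sigma_I Gaussian kernel widths (normalized position units).
#' @param W0_EE,W0_EI,W0_II,W0_IE per-presynaptic-neuron row budgets (nS).
#' @param W_UI uniform inhibitory weight budget (nS).
#' @return A list of class `"ftsts_connectivity_spec"`.
#' @examples
#' connectivity_spec(N_E = 10, N_I = 10)
#' @export
connectivity_spec <- function(N_E = 500, N_I = 500, sigma_E = 0.02,
                              sigma_I = 0.03, W0_EE = 104, W0_EI = 100,
                              W0_II = 250, W0_IE = 250, W_UI = 50) {
  if (N_E < 1 || N_I < 1) stop("population sizes must be >= 1", call. = FALSE)
  if (sigma_E <= 0 || sigma_I <= 0) stop("sigmas must be > 0", call. = FALSE)
  if (min(W0_EE, W0_EI, W0_II, W0_IE, W_UI) < 0) {
    stop("weight scalings must be >= 0", call. = FALSE)
  }
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 sigma_E = sigma_E, sigma_I = sigma_I, W0_EE = W0_EE,
                 W0_EI = W0_EI, W0_II = W0_II, W0_IE = W0_IE, W_UI = W_UI),
            class = "ftsts_connectivity_spec")
}

gaussian_kernel_matrix <- function(N_pre, N_post, sigma) {
  x_pre <- (seq_len(N_pre) - 1L) / N_pre
  x_post <- (seq_len(N_post) - 1L) / N_post
  d <- abs(outer(x_pre, x_post, `-`))
  stats::dnorm(d, mean = 0, sd = sigma)
}

row_normalized <- function(K, W0) {
  rs <- rowSums(K)
  if (any(rs == 0)) {
    stop("connectivity kernel underflowed to an all-zero row; ",
         "sigma is too small for this population size", call. = FALSE)
  }
  K / rs * W0
}

#' Build the static synaptic weight matrices
#'
#' Deterministically constructs the four dense base matrices (presynaptic
#' index in rows, postsynaptic index in columns). The Gaussian part of every
#' presynaptic row sums exactly to its `W0` budget; `W_II` and `W_IE` carry an
#' extra uniform `W_UI / N_target` per entry. The line is open (no
#' wrap-around): row normalization absorbs edge truncation.
#'
#' @param spec a [connectivity_spec()].
#' @return A list of class `"ftsts_weights"` with dense matrices `W_EE`
#'   (`N_E x N_E`), `W_EI` (`N_E x N_I`), `W_II` (`N_I x N_I`) and `W_IE`
#'   (`N_I x N_E`), all in nS, plus the `spec`.
#' @examples
#' W <- build_connectivity(connectivity_spec(N_E = 10, N_I = 10))
#' rowSums(W$W_EE)  # every row sums to W0_EE
#' @export
build_connectivity <- function(spec) {
  stopifnot(inherits(spec, "ftsts_connectivity_spec"))
  W_EE <- row_normalized(gaussian_kernel_matrix(spec$N_E, spec$N_E, spec$sigma_E),
                         spec$W0_EE)
  W_EI <- row_normalized(gaussian_kernel_matrix(spec$N_E, spec$N_I, spec$sigma_E),
                         spec$W0_EI)
  W_II <- row_normalized(gaussian_kernel_matrix(spec$N_I, spec$N_I, spec$sigma_I),
                         spec$W0_II) + spec$W_UI / spec$N_I
  W_IE <- row_normalized(gaussian_kernel_matrix(spec$N_I, spec$N_E, spec$sigma_I),
                         spec$W0_IE) + spec$W_UI / spec$N_E
  structure(list(W_EE = W_EE, W_EI = W_EI, W_II = W_II, W_IE = W_IE,
                 spec = spec),
            class = "ftsts_weights")
}

#' Write / read a weight matrix as CSV
#'
#' Plain-text round trip for small test networks: a dense matrix with
#' presynaptic rows, no row or column names.
#'
#' @param W a numeric matrix.
#' @param path file path.
#' @return `write_weights_csv` returns `path` invisibly; `read_weights_csv`
#'   returns the matrix.
#' @export
write_weights_csv <- function(W, path) {
  utils::write.table(W, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
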