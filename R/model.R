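#' CNN architecture configuration
#'
#' The classifier has three weight-independent convolutional branches (one
#' per signal) with the layout of the front of VGG16: five blocks of 3x3
#' stride-1 same-padding convolutions with ReLU, each block closed by a 2x2
#' stride-2 max pool; blocks 1-2 hold two convolutions, blocks 3-5 three.
#' A global max pool after block 5 turns each branch's feature map into a
#' `branch_feature_dim`-vector regardless of input side, the three vectors
#' are concatenated, and a dense layer with a single sigmoid unit outputs
#' `P(stressed)`.
#'
#' @param block_filters integer vector of 5 filter counts
#'   (default `c(32, 64, 128, 256, 256)`).
#' @param convs_per_block integer vector of 5 convolution counts per block
#'   (default `c(2, 2, 3, 3, 3)`).
#' @return an object of class `contrp_arch_config`; `branch_feature_dim`
#'   equals `block_filters[5]` and `repr_dim` is three times that.
#' @export
arch_config <- function(block_filters = c(32, 64, 128, 256, 256),
                        convs_per_block = c(2, 2, 3, 3, 3)) {
  if (length(block_filters) != 5L || any(block_filters < 1) ||
      any(block_filters != round(block_filters)))
    abort_config("block_filters must be 5 positive integers")
  if (length(convs_per_block) != 5L || any(convs_per_block < 1) ||
      any(convs_per_block != round(convs_per_block)))
    abort_config("convs_per_block must be 5 positive integers")
  structure(list(block_filters = as.integer(block_filters),
                 convs_per_block = as.integer(convs_per_block),
                 kernel = 3L, pool = 2L,
                 branch_feature_dim = as.integer(block_filters[5L]),
                 repr_dim = 3L * as.integer(block_filters[5L])),
            class = "contrp_arch_config")
}

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 0.001).
#' @param batch_size minibatch size (default 4).
#' @param epochs training epochs (default 15).
#' @param momentum SGD momentum (default 0, plain SGD).
#' @param seed integer seed governing weight initialization and shuffling.
#' @return an object of class `contrp_train_config`.  Loss is binary
#'   cross-entropy.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 4, epochs = 15,
                         momentum = 0, seed = 1) {
  if (!is_scalar_num(learning_rate) || learning_rate < 0)
    abort_config("learning_rate must be >= 0")
  if (!is_count(batch_size)) abort_config("batch_size must be >= 1")
  if (!is.numeric(epochs) || length(epochs) != 1L || epochs < 0 ||
      epochs != round(epochs))
    abort_config("epochs must be a non-negative integer")
  if (!is_scalar_num(momentum) || momentum < 0 || momentum >= 1)
    abort_config("momentum must be in [0, 1)")
  structure(list(learning_rate = as.double(learning_rate),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 momentum = as.double(momentum),
                 seed = as.integer(seed)),
            class = "contrp_train_config")
}

# channel plan of one branch: data.frame of (c_in, c_out) per conv layer
branch_layer_plan <- function(arch) {
  c_in <- integer(0); c_out <- integer(0)
  prev <- 1L
  for (b in 1:5) {
    for (k in seq_len(arch$convs_per_block[b])) {
      c_in <- c(c_in, prev)
      c_out <- c(c_out, arch$block_filters[b])
      prev <- arch$block_filters[b]
    }
  }
  data.frame(c_in = c_in, c_out = c_out)
}

# He-uniform initialization: preserves activation variance through deep
# ReLU stacks, so 13-conv-layer branches remain trainable from scratch
he_uniform <- function(fan_in, n) {
  lim <- sqrt(6 / fan_in)
  stats::runif(n, -lim, lim)
}

#' Build an untrained multimodal CNN
#'
#' Initializes the three branches and the sigmoid head with He-uniform
#' weights and zero biases, deterministically from `seed`.  He scaling is
#' used because each branch stacks 13 ReLU convolutions; fan-average
#' schemes shrink activations by roughly `2^(-13/2)` over such a stack,
#' leaving the global-max-pooled features too small to train quickly.
#'
#' @param arch an [arch_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `contrp_cnn`: list with `arch`, `branches`
#'   (named list `fgsr`, `hgsr`, `hr` of conv-layer weight lists) and `head`.
#' @export
build_model <- function(arch = arch_config(), seed = 1) {
  if (!inherits(arch, "contrp_arch_config")) abort_config("arch must be an arch_config")
  plan <- branch_layer_plan(arch)
  with_seed(seed, {
    branches <- lapply(c("fgsr", "hgsr", "hr"), function(nm) {
      lapply(seq_len(nrow(plan)), function(i) {
        ci <- plan$c_in[i]; co <- plan$c_out[i]
        list(W = array(he_uniform(9 * ci, 9 * ci * co), dim = c(3, 3, ci, co)),
             b = numeric(co))
      })
    })
    names(branches) <- c("fgsr", "hgsr", "hr")
    fd <- arch$branch_feature_dim
    head <- list(w = he_uniform(3 * fd, 3 * fd), b = 0)
    structure(list(arch = arch, branches = branches, head = head),
              class = "contrp_cnn")
  })
}

#' @export
print.contrp_cnn <- function(x, ...) {
  cat(sprintf(
    "<multimodal CNN: 3 branches x %d conv layers, filters %s;\n  branch feature dim %d, representation dim %d, %s parameters>\n",
    sum(x$arch$convs_per_block),
    paste(x$arch$block_filters, collapse = ","),
    x$arch$branch_feature_dim, x$arch$repr_dim,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a [build_model()] object.
#' @return total number of trainable scalars over the three branches and the
#'   head.
#' @export
count_parameters <- function(model) {
  n <- 0
  for (br in model$branches)
    for (L in br) n <- n + length(L$W) + length(L$b)
  n + length(model$head$w) + 1L
}

# triples -> plain list-of-3-matrices for the C++ kernels
triples_for_cpp <- function(triples) {
  lapply(triples, function(s) list(s$rp_fgsr, s$rp_hgsr, s$rp_hr))
}

check_sides <- function(triples, require_equal = FALSE) {
  sides <- vapply(triples, triple_side, numeric(1))
  if (require_equal && length(unique(sides)) > 1L)
    abort_data("all triples in a batch must have plots of the same side")
  invisible(sides)
}

#' Predict stress probabilities
#'
#' @param model a (possibly trained) [build_model()] object.
#' @param triples list of sample triples (see [make_sample_triples()]).
#' @return list with `p` (numeric vector of `P(stressed)` in (0,1)) and
#'   `label` (`"stressed"` iff `p >= 0.5`, the documented tie-break).
#' @export
predict_cnn <- function(model, triples) {
  if (!inherits(model, "contrp_cnn")) abort_data("model must be a contrp_cnn")
  if (length(triples) == 0L) return(list(p = numeric(0), label = character(0)))
  check_sides(triples)
  out <- cnn_forward_cpp(model$branches, model$head$w, model$head$b,
                         triples_for_cpp(triples), model$arch$convs_per_block,
                         FALSE)
  list(p = out$p, label = ifelse(out$p >= 0.5, "stressed", "relaxed"))
}

#' Extract pre-head representation vectors
#'
#' Returns the concatenated branch features fed to the dense head; columns
#' `1:fd` come from the FGSR branch, `fd + 1:fd` from HGSR and
#' `2 fd + 1:fd` from HR, where `fd` is the branch feature dimension
#' (256 by default, so rows are 768-dimensional).
#'
#' @param model a [build_model()] object.
#' @param triples list of sample triples with equal plot sides.
#' @return numeric matrix, one row per triple.
#' @export
extract_representation <- function(model, triples) {
  if (!inherits(model, "contrp_cnn")) abort_data("model must be a contrp_cnn")
  if (length(triples) == 0L)
    return(matrix(numeric(0), 0, model$arch$repr_dim))
  check_sides(triples, require_equal = TRUE)
  out <- cnn_forward_cpp(model$branches, model$head$w, model$head$b,
                         triples_for_cpp(triples), model$arch$convs_per_block,
                         TRUE)
  out$repr
}

#' Train the multimodal CNN
#'
#' Minibatch stochastic gradient descent on binary cross-entropy.  Sample
#' order is reshuffled every epoch; shuffling is driven by `cfg$seed`, so a
#' run is reproducible bit-for-bit on one platform.
#'
#' @param model a [build_model()] object.
#' @param triples training sample triples containing both classes.
#' @param cfg a [train_config()].
#' @return list with `model` (trained `contrp_cnn`) and `loss` (per-epoch
#'   mean training loss; empty when `epochs = 0`).
#' @export
train_cnn <- function(model, triples, cfg = train_config()) {
  if (!inherits(model, "contrp_cnn")) abort_data("model must be a contrp_cnn")
  y <- triple_y(triples)
  if (length(unique(y)) < 2L)
    abort_data("training data must contain both classes")
  if (cfg$epochs == 0L) return(list(model = model, loss = numeric(0)))
  check_sides(triples)
  n <- length(triples)
  orders <- with_seed(cfg$seed, {
    t(vapply(seq_len(cfg$epochs), function(e) sample.int(n), integer(n)))
  })
  if (n == 1L) orders <- matrix(orders, nrow = cfg$epochs)
  res <- cnn_train_cpp(model$branches, model$head$w, model$head$b,
                       triples_for_cpp(triples), y,
                       cfg$learning_rate, cfg$batch_size,
                       orders, model$arch$convs_per_block, cfg$momentum)
  model$branches <- res$branches
  model$head <- list(w = res$head_w, b = res$head_b)
  list(model = model, loss = res$loss)
}
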