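#' Hyperparameters controlling an SDGAE fit
#'
#' Collects every tunable of the pipeline. The defaults are the settings
#' used at full dataset scale: neighbour decay `eta = 0.8`, `K = 10`
#' nearest known neighbours for densification, `p = 5` nearest
#' neighbours for the spatial-consistency graph, loss weights
#' `lambda_l = 1e-5` (Tikhonov), `lambda_d = lambda_t = 0.001`
#' (drug/target Laplacian terms), 5000 training epochs with Adam at
#' learning rate `1e-4`, and a boosted-tree learning rate of `0.02`.
#'
#' `sdgae_control(profile = "desk")` switches to a desk-scale profile
#' (smaller embedding dimensions, 500 epochs, 200 boosting rounds)
#' suitable for the bundled synthetic benchmark; all other values are
#' unchanged. Any explicitly named argument overrides its profile value.
#'
#' @param eta neighbour decay in (0, 1] for the weighted
#'   K-nearest-known-neighbours imputation.
#' @param K number of known neighbours used by the imputation.
#' @param p neighbour count of the spatial-consistency graph.
#' @param lambda_l,lambda_d,lambda_t non-negative weights of the
#'   Tikhonov, drug-Laplacian and target-Laplacian loss terms.
#' @param hidden_dim,embed_dim GCN hidden-layer width `l` and embedding
#'   dimension `k`.
#' @param epochs training epochs for the autoencoder.
#' @param lr_repr Adam learning rate of the representation stage.
#' @param lr_gbdt learning rate of the boosted-tree classifier.
#' @param n_rounds boosting rounds of the classifier.
#' @param n_leaves maximum leaves per tree.
#' @param n_folds cross-validation folds.
#' @param seed integer seed covering weight initialisation, Gaussian
#'   reference sampling, fold assignment and tree fitting.
#' @param use_ddm densify the interaction matrix before building the
#'   heterogeneous network (ablation switch).
#' @param use_scc include the spatial-consistency loss (ablation switch).
#' @param use_gan include the adversarial regulariser (ablation switch).
#' @param features node feature matrix content: `"similarity"` (fused
#'   similarities on the diagonal blocks, densified interactions off
#'   diagonal) or `"adjacency"` (pure topology).
#' @param side_combine how the drug-side and target-side imputation
#'   estimates are combined: `"mean"` or `"max"`.
#' @param median_rule median convention for an even number of imputed
#'   values: `"lower"` keeps the threshold an attained value,
#'   `"interpolate"` averages the two central values.
#' @param profile `"paper"` (defaults above) or `"desk"`.
#' @param ... ignored; present so configuration lists can be spliced.
#' @return A named list of class `sdgae_control`.
#' @export
sdgae_control <- function(eta = 0.8, K = 10L, p = 5L,
                          lambda_l = 1e-5, lambda_d = 0.001,
                          lambda_t = 0.001,
                          hidden_dim = 500L, embed_dim = 200L,
                          epochs = 5000L, lr_repr = 1e-4,
                          lr_gbdt = 0.02, n_rounds = 500L,
                          n_leaves = 31L, n_folds = 10L, seed = 1L,
                          use_ddm = TRUE, use_scc = TRUE, use_gan = TRUE,
                          features = c("similarity", "adjacency"),
                          side_combine = c("mean", "max"),
                          median_rule = c("lower", "interpolate"),
                          profile = c("paper", "desk"), ...) {
  profile <- match.arg(profile)
  ctrl <- list(
    eta = eta, K = as.integer(K), p = as.integer(p),
    lambda_l = lambda_l, lambda_d = lambda_d, lambda_t = lambda_t,
    hidden_dim = as.integer(hidden_dim), embed_dim = as.integer(embed_dim),
    epochs = as.integer(epochs), lr_repr = lr_repr,
    lr_gbdt = lr_gbdt, n_rounds = as.integer(n_rounds),
    n_leaves = as.integer(n_leaves), n_folds = as.integer(n_folds),
    seed = as.integer(seed),
    use_ddm = isTRUE(use_ddm), use_scc = isTRUE(use_scc),
    use_gan = isTRUE(use_gan),
    features = match.arg(features),
    side_combine = match.arg(side_combine),
    median_rule = match.arg(median_rule),
    profile = profile
  )
  if (profile == "desk") {
    desk <- list(hidden_dim = 64L, embed_dim = 32L, epochs = 500L,
                 n_rounds = 200L)
    given <- names(match.call())[-1]
    for (nm in setdiff(names(desk), given)) ctrl[[nm]] <- desk[[nm]]
  }
  stopifnot(ctrl$eta > 0, ctrl$eta <= 1, ctrl$K >= 1L, ctrl$p >= 1L,
            ctrl$lambda_l >= 0, ctrl$lambda_d >= 0, ctrl$lambda_t >= 0,
            ctrl$hidden_dim >= 1L, ctrl$embed_dim >= 1L,
            ctrl$epochs >= 1L, ctrl$lr_repr > 0, ctrl$lr_gbdt > 0,
            ctrl$n_folds >= 2L)
  class(ctrl) <- "sdgae_control"
  ctrl
}

#' Read a run configuration file
#'
#' A flat YAML-style `key: value` document holding any subset of
#' [sdgae_control()] fields; unspecified keys take the profile defaults.
#'
#' @param path configuration file.
#' @param profile base profile for unspecified keys.
#' @return An `sdgae_control` list.
#' @export
read_sdgae_config <- function(path, profile = "paper") {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(formals(sdgae_control)))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg$profile <- if (!is.null(cfg$profile)) cfg$profile else profile
  do.call(sdgae_control, cfg)
}

#' @export
print.sdgae_control <- function(x, ...) {
  cat(sprintf("sdgae_control (%s profile)\n", x$profile))
  flat <- x[setdiff(names(x), "profile")]
  cat(paste0("  ", names(flat), " = ", unlist(lapply(flat, format)),
             collapse = "\n"), "\n")
  invisible(x)
}
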