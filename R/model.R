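# Full model assembly: shared encoder over masked lobe subvolumes, gated
# region attention, graph attention over the lobe adjacency, multi-modal
# fusion, and linear prediction heads. A model object holds `params`
# (nested list of numeric arrays), `cfg`, and mutable `state` (class
# centroids, normalization statistics, co-occurrence matrix, zone mask).

# parameter leaves that are state or structure, never optimized
PARAM_SKIP <- c("heads", "combine", "d", "n_in", "n_out", "dropout",
                "run_mean", "run_var")

# apply f to every trainable numeric leaf, preserving structure
params_map <- function(params, f, path = "") {
  out <- params
  for (nm in names(params)) {
    x <- params[[nm]]
    if (nm %in% PARAM_SKIP || is.character(x)) next
    out[[nm]] <- if (is.list(x)) params_map(x, f, paste0(path, nm, "."))
    else f(x, paste0(path, nm))
  }
  out
}

wrap_params <- function(params) params_map(params, function(x, nm) ad_param(x))

collect_grads <- function(wrapped) {
  params_map(wrapped, function(x, nm) {
    g <- x$grad
    if (is.null(g)) zeros_like(x$value) else g
  })
}

unwrap_params <- function(wrapped) params_map(wrapped, function(x, nm) ad_value(x))

#' Flatten trainable parameters into one named numeric vector
#' @param params nested parameter list.
#' @return Named numeric vector (names are dotted paths).
#' @export
flatten_params <- function(params) {
  acc <- list()
  walk <- function(p, path) {
    for (nm in names(p)) {
      x <- p[[nm]]
      if (nm %in% PARAM_SKIP || is.character(x)) next
      if (is.list(x)) walk(x, paste0(path, nm, "."))
      else acc[[paste0(path, nm)]] <<- as.numeric(x)
    }
  }
  walk(params, "")
  unlist(acc)
}

#' Write a flat vector back into the nested parameter structure
#' @param params nested parameter list (provides shapes).
#' @param flat numeric vector from [flatten_params()].
#' @return Updated nested list.
#' @export
unflatten_params <- function(params, flat) {
  pos <- 0L
  walk <- function(p) {
    for (nm in names(p)) {
      x <- p[[nm]]
      if (nm %in% PARAM_SKIP || is.character(x)) next
      if (is.list(x)) p[[nm]] <- walk(x)
      else {
        n <- length(x)
        v <- unname(flat[(pos + 1L):(pos + n)])
        pos <<- pos + n
        if (!is.null(dim(x))) dim(v) <- dim(x)
        p[[nm]] <- v
      }
    }
    p
  }
  out <- walk(params)
  stopifnot(pos == length(flat))
  out
}

#' Build a model for a phantom cohort
#'
#' @param phantom_cfg the [phantom_config()] the data came from (grid, K,
#'   labels).
#' @param channels encoder channels C.
#' @param blocks encoder residual blocks.
#' @param kernel encoder kernel edge.
#' @param d1,d2 tabular projection widths.
#' @param tab_hidden hidden width of the tabular perceptrons.
#' @param graph_d refined node embedding width d.
#' @param graph_heads attention heads.
#' @param adjacency_scheme lobe adjacency scheme (see [build_adjacency()]).
#' @param adjacency custom adjacency for scheme "custom".
#' @param normalize_attention use the normalized (convex-combination)
#'   variant of the attended summary, so the regions compete for weight.
#' @param class_head `"fused"`: the classifier reads the fused embedding z
#'   (classification flows through the attended summary, which is what
#'   lets the gates localize pathology); `"fused_graph"`: z concatenated
#'   with the graph descriptor.
#' @param gate_scale initial scale of the attention gate parameters
#'   (pooled descriptors have small magnitude after global pooling, so the
#'   gate starts steeper than the rest of the network).
#' @param seed integer seed for all weight draws.
#' @return A `lobenet_model` list with `params`, `cfg`, `state`.
#' @export
build_model <- function(phantom_cfg, channels = 8L, blocks = 1L, kernel = 3L,
                        d1 = 8L, d2 = 8L, tab_hidden = 16L,
                        graph_d = NULL, graph_heads = 2L,
                        adjacency_scheme = "lobar", adjacency = NULL,
                        class_head = c("fused", "fused_graph"),
                        normalize_attention = TRUE,
                        gate_scale = 3, seed = 1L) {
  class_head <- match.arg(class_head)
  K <- phantom_cfg$n_regions
  C <- as.integer(channels)
  graph_d <- as.integer(graph_d %||% C)
  n_classes <- if (phantom_cfg$label_mode == "presence") 2L else K
  enc_cfg <- encoder_config(channels = C, blocks = blocks, kernel = kernel)
  zlen <- C + d1 + d2
  head_in <- zlen + K * graph_d
  lobes <- carve_lobe_masks(phantom_cfg$grid_size, K)
  cls_in <- if (class_head == "fused") zlen else head_in
  params <- with_seed(substream_seed(seed, "init"), list(
    enc = init_encoder_params(enc_cfg, seed = substream_seed(seed, "enc")),
    att = init_attention_params(C, scale = gate_scale,
                                seed = substream_seed(seed, "att")),
    graph = init_graph_params(C, d = graph_d, heads = graph_heads,
                              seed = substream_seed(seed, "graph")),
    tab = init_tabular_params(phantom_cfg$n_clinical, phantom_cfg$n_metadata,
                              d1 = d1, d2 = d2, hidden = tab_hidden,
                              seed = substream_seed(seed, "tab")),
    simplex_logits = numeric(K),
    sym_T = diag(C),
    psi = list(w = rnorm(zlen, sd = 0.1), b = 0),
    cls = list(W = matrix(rnorm(n_classes * cls_in, sd = sqrt(1 / cls_in)),
                          n_classes, cls_in),
               b = numeric(n_classes)),
    ml = list(W = matrix(rnorm(phantom_cfg$n_labels * head_in, sd = sqrt(1 / head_in)),
                         phantom_cfg$n_labels, head_in),
              b = numeric(phantom_cfg$n_labels)),
    dec = init_decoder_params(C, kernel, seed = substream_seed(seed, "dec")),
    aligner = init_aligner_params()))
  feat_dim <- rep(phantom_cfg$grid_size %/% 2L, 3)
  masks_ds <- lapply(lobes$masks, downsample_mask, target_dim = feat_dim)
  zone <- pmin(Reduce(`+`, masks_ds), 1)
  structure(list(
    params = params,
    cfg = list(phantom = phantom_cfg, enc = enc_cfg, K = K,
               d1 = d1, d2 = d2, graph_d = graph_d,
               n_classes = n_classes, class_head = class_head,
               normalize_attention = isTRUE(normalize_attention),
               region_names = lobes$names, side = lobes$side,
               adj = build_adjacency(K, adjacency_scheme, adjacency),
               zlen = zlen, seed = seed),
    state = list(centroids = list(), zscore = NULL, cooc = NULL,
                 zone = zone, masks_ds = masks_ds,
                 momentum_enc = params$enc)),
    class = "lobenet_model")
}

# standardize a study's tabular vectors using the model's fitted z-score
std_tabular <- function(study, state) {
  if (is.null(state$zscore)) return(study)
  study$clinical <- zscore_apply(study$clinical, state$zscore$clinical)
  study$metadata <- zscore_apply(study$metadata, state$zscore$metadata)
  study
}

#' Forward pass for one study
#'
#' Runs decomposition, shared encoding, gated attention, graph reasoning,
#' fusion, and the prediction heads. With `params = NULL` the stored
#' numeric parameters are used (pure inference); during training pass the
#' wrapped (adnode) parameters.
#'
#' @param model a [build_model()] object.
#' @param study a `phantom_study` (tabular vectors already standardized by
#'   the caller or via the model state).
#' @param params optional wrapped parameter list.
#' @param train training mode (enables attention/tabular dropout, which
#'   draws from the current RNG stream).
#' @return List with per-stage results: `h` (pooled descriptors), `alpha`,
#'   `r`, `fmaps`, `hp` (refined node embeddings), `gvec`, `v_glob`,
#'   `heatmap`, `z` (fused), `logits`, `shat`, `ml_pred`.
#' @export
forward_study <- function(model, study, params = NULL, train = FALSE) {
  p <- params %||% model$params
  cfg <- model$cfg
  study <- std_tabular(study, model$state)
  subs <- decompose_regions(study$volume, study$masks)
  fmaps <- lapply(subs, encode_region, params = p$enc, config = cfg$enc)
  # region descriptors pool over the lobe's own support on the feature
  # grid, so a small lobe's features are not diluted by the background;
  # the gates read the plain globally pooled descriptor, whose only
  # region-to-region variation is the abnormality itself
  h <- Map(t_gap_masked, fmaps, model$state$masks_ds)
  alpha <- gated_attention(lapply(fmaps, t_gap), p$att)
  # weights are normalized first (sigmoid outputs are strictly positive, so
  # the total never vanishes), then dropout perturbs them ahead of the sum;
  # the entropy regularizer and any localization readout see the raw gates
  # (log 0 is undefined)
  alpha_sum <- if (isTRUE(cfg$normalize_attention)) {
    tot <- Reduce(t_add, alpha)
    lapply(alpha, function(a) t_div(a, tot))
  } else alpha
  if (train) alpha_sum <- attention_dropout(alpha_sum, rate = 0.1, train = TRUE)
  r <- attended_summary(h, alpha_sum)
  hp <- message_pass(h, cfg$adj, p$graph)
  gvec <- concat_descriptor(hp)
  f_glob <- encode_region(study$volume, p$enc, cfg$enc)
  v_glob <- t_gap(f_glob)
  heatmap <- t_chanmean(f_glob)
  f_clin <- project_tabular(study$clinical, "clinical", p$tab, train = train)
  f_mod <- project_tabular(study$metadata, "metadata", p$tab, train = train)
  fe <- fuse(r, f_clin, f_mod)
  z <- fe$z
  # the classifier reads z (default) or z plus the graph descriptor; the
  # multi-label head always sees the graph descriptor; the severity head
  # reads z alone, as psi(phi(x))
  head_in <- t_concat(list(z, gvec))
  cls_in <- if (cfg$class_head == "fused") z else head_in
  logits <- t_add(t_matvec(p$cls$W, cls_in), p$cls$b)
  shat <- severity_head(z, p$psi)
  ml_pred <- t_sigmoid(t_add(t_matvec(p$ml$W, head_in), p$ml$b))
  list(h = h, alpha = alpha, r = r, fmaps = fmaps, hp = hp, gvec = gvec,
       v_glob = v_glob, heatmap = heatmap, z = z, fused = fe,
       logits = logits, shat = shat, ml_pred = ml_pred)
}

# cross-entropy of one sample: logsumexp(logits) - logits[y + 1]
ce_loss <- function(logits, y) {
  mx <- max(ad_value(logits))
  t_sub(t_add(t_log(t_sum(t_exp(t_sub(logits, mx)))), mx),
        t_index(logits, y + 1L))
}

# momentum-encoder global embedding of a volume (numeric, no gradients)
momentum_embed <- function(model, volume) {
  ad_value(t_gap(encode_region(volume, model$state$momentum_enc, model$cfg$enc)))
}
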