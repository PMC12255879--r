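# The multimodal affinity model: four encoder branches (dilated-convolution
# protein encoder, pocket-ligand cross-attention, E(n)-invariant pocket
# encoder, attentive-fingerprint ligand encoder), the three-step SAGE-based
# environment-aware heterogeneous message passing over the complex graph,
# and the fusion MLP regressor.

#' Model configuration
#'
#' Architecture hyperparameters and the per-branch ablation switches. The
#' dilation schedules (five levels `[1,2,4,8,16]` for the protein encoder,
#' four levels `[1,2,4,8]` for the ligand side of the sequence-complex
#' module), two attention heads, and the three-layer depths of the graph
#' encoders are fixed defaults of the architecture; hidden widths are free.
#'
#' @param hidden_dim width of every branch embedding (default 128).
#' @param attention_heads number of cross-attention heads (default 2);
#'   must divide `hidden_dim`.
#' @param protein_dilations dilation schedule of the protein encoder.
#' @param ligand_dilations dilation schedule of the ligand convolution stack.
#' @param egnn_layers,hgt_layers,attentivefp_layers,attentivefp_timesteps
#'   graph-encoder depths.
#' @param fusion_hidden widths of the two fusion MLP hidden layers.
#' @param branches named logical list of ablation switches: `protein`,
#'   `sequence_complex`, `covalent`, `noncovalent`, `environment_nodes`.
#'   Disabling removes the module (its parameters are never created).
#' @return object of class `ModelConfig`.
#' @export
model_config <- function(hidden_dim = 128L,
                         attention_heads = 2L,
                         protein_dilations = c(1L, 2L, 4L, 8L, 16L),
                         ligand_dilations = c(1L, 2L, 4L, 8L),
                         egnn_layers = 3L,
                         hgt_layers = 3L,
                         attentivefp_layers = 3L,
                         attentivefp_timesteps = 2L,
                         fusion_hidden = NULL,
                         branches = list()) {
  br <- list(protein = TRUE, sequence_complex = TRUE, covalent = TRUE,
             noncovalent = TRUE, environment_nodes = TRUE)
  for (nm in names(branches)) {
    if (!nm %in% names(br)) stop("unknown branch flag: ", nm)
    br[[nm]] <- isTRUE(branches[[nm]])
  }
  if (!any(unlist(br[c("protein", "sequence_complex", "covalent", "noncovalent")]))) {
    stop("all branches disabled")
  }
  if (hidden_dim %% attention_heads != 0L) {
    stop("hidden_dim must be divisible by attention_heads")
  }
  stopifnot(egnn_layers >= 1L, hgt_layers >= 1L, attentivefp_layers >= 1L,
            attentivefp_timesteps >= 1L)
  if (is.null(fusion_hidden)) fusion_hidden <- c(2L * hidden_dim, hidden_dim)
  structure(list(
    hidden_dim = as.integer(hidden_dim),
    attention_heads = as.integer(attention_heads),
    key_dim = as.integer(hidden_dim / attention_heads),
    protein_dilations = as.integer(protein_dilations),
    ligand_dilations = as.integer(ligand_dilations),
    egnn_layers = as.integer(egnn_layers),
    hgt_layers = as.integer(hgt_layers),
    attentivefp_layers = as.integer(attentivefp_layers),
    attentivefp_timesteps = as.integer(attentivefp_timesteps),
    fusion_hidden = as.integer(fusion_hidden),
    branches = br
  ), class = "ModelConfig")
}

#' Initialise model parameters
#'
#' Glorot-uniform weights, zero biases; only the parameters of enabled
#' branches are created, so ablation removes modules rather than zeroing
#' them.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for reproducible initialisation.
#' @return nested named list of parameter matrices.
#' @export
init_model_params <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ModelConfig"))
  set.seed(seed)
  h <- cfg$hidden_dim
  p <- list()
  nfuse <- 0L
  if (cfg$branches$protein) {
    p$protein <- list(
      embed = init_linear(40L, h),
      conv = lapply(cfg$protein_dilations, function(d) init_conv1d(h, h)),
      proj = init_linear(length(cfg$protein_dilations) * h, h)
    )
    nfuse <- nfuse + 1L
  }
  if (cfg$branches$sequence_complex) {
    attn <- function() list(Wq = init_weight(h, h), Wk = init_weight(h, h),
                            Wv = init_weight(h, h), Wo = init_weight(h, h))
    p$seqcplx <- list(
      poc_embed = init_linear(40L, h),
      lig_embed = init_linear(18L, h),
      attn_pq = attn(),   # pocket as query, ligand as key/value
      attn_lq = attn(),   # ligand as query, pocket as key/value
      poc_conv = init_conv1d(h, h),
      lig_conv = lapply(cfg$ligand_dilations, function(d) init_conv1d(h, h)),
      lig_proj = init_linear(length(cfg$ligand_dilations) * h, h),
      out = init_linear(2L * h, h)
    )
    nfuse <- nfuse + 1L
  }
  if (cfg$branches$covalent) {
    p$egnn <- list(
      embed = init_linear(21L, h),
      layers = lapply(seq_len(cfg$egnn_layers), function(i) list(
        msg1 = init_linear(2L * h + 1L, h), msg2 = init_linear(h, h),
        xw = init_linear(h, 1L),
        upd1 = init_linear(2L * h, h), upd2 = init_linear(h, h)
      )),
      proj = init_linear(cfg$egnn_layers * h, h)
    )
    p$afp <- list(
      embed = init_linear(18L, h),
      layers = lapply(seq_len(cfg$attentivefp_layers), function(i) list(
        align = init_linear(if (i == 1L) 2L * h + 12L else 2L * h, 1L),
        msg = init_linear(h, h),
        gru = init_gru(h, h)
      )),
      read_align = init_linear(2L * h, 1L),
      read_gru = init_gru(h, h)
    )
    nfuse <- nfuse + 2L
  }
  if (cfg$branches$noncovalent) {
    p$hgt <- list(
      c_embed = init_linear(18L, h),
      e_embed = init_linear(5L, h),
      layers = lapply(seq_len(cfg$hgt_layers), function(i) list(
        s1_self = init_linear(h, h), s1_nbr = init_weight(h, h),
        s2_self = init_linear(h, h), s2_nbr = init_weight(h, h),
        s3_self = init_linear(h, h), s3_nbr = init_weight(h, h)
      )),
      edge_w = list(a = matrix(-0.5, 1L, 1L), b = matrix(1, 1L, 1L)),
      pool1 = init_linear(2L * h, h), pool2 = init_linear(h, h)
    )
    nfuse <- nfuse + 1L
  }
  p$fusion <- list(
    l1 = init_linear(nfuse * h, cfg$fusion_hidden[1L]),
    l2 = init_linear(cfg$fusion_hidden[1L], cfg$fusion_hidden[2L]),
    l3 = init_linear(cfg$fusion_hidden[2L], 1L)
  )
  p
}

# ---- branch forwards (tape level) ------------------------------------------

# x: node id of L x 40 matrix (valid rows only); returns 1 x h node
fwd_protein <- function(tp, bp, x, mask, dilations) {
  h <- nn_linear(tp, x, bp$embed)
  h <- ad_relu(tp, h)
  if (!all(mask)) {
    h <- ad_mulc(tp, h, matrix(as.numeric(mask), length(mask), ncol(ad_value(tp, h))))
  }
  outs <- integer(0)
  cur <- h
  for (li in seq_along(dilations)) {
    cur <- nn_conv1d_dilated(tp, cur, mask, bp$conv[[li]], dilations[li])
    outs <- c(outs, cur)
  }
  cat5 <- ad_cbind(tp, outs)
  pooled <- ad_masked_mean(tp, cat5, mask)
  nn_linear(tp, pooled, bp$proj)
}

# scaled dot-product multi-head cross attention; returns n_q x h node
fwd_attention_dir <- function(tp, q_in, kv_in, ap, heads, dk, kmask) {
  Q <- ad_mm(tp, q_in, ap$Wq)
  K <- ad_mm(tp, kv_in, ap$Wk)
  V <- ad_mm(tp, kv_in, ap$Wv)
  ctxs <- integer(0)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    Qh <- ad_mulc_cols(tp, Q, cols)
    Kh <- ad_mulc_cols(tp, K, cols)
    Vh <- ad_mulc_cols(tp, V, cols)
    sc <- ad_scale(tp, ad_mm(tp, Qh, ad_t(tp, Kh)), 1 / sqrt(dk))
    A <- ad_softmax_rows(tp, sc, kmask)
    ctxs <- c(ctxs, ad_mm(tp, A, Vh))
  }
  ctx <- ad_cbind(tp, ctxs)
  ad_mm(tp, ctx, ap$Wo)
}

# column slice as an op (select head columns)
ad_mulc_cols <- function(tp, a, cols) {
  force(a)
  av <- tp$v[[adk(a)]]
  ad_node(tp, av[, cols, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, cols] <- g
    list(out)
  })
}

fwd_seqcplx <- function(tp, bp, poc_x, poc_mask, lig_x, lig_mask, cfg) {
  h <- cfg$hidden_dim
  pe <- ad_relu(tp, nn_linear(tp, poc_x, bp$poc_embed))
  le <- ad_relu(tp, nn_linear(tp, lig_x, bp$lig_embed))
  if (!all(poc_mask)) pe <- ad_mulc(tp, pe, matrix(as.numeric(poc_mask), length(poc_mask), h))
  if (!all(lig_mask)) le <- ad_mulc(tp, le, matrix(as.numeric(lig_mask), length(lig_mask), h))
  dk <- cfg$key_dim
  poc_att <- fwd_attention_dir(tp, pe, le, bp$attn_pq, cfg$attention_heads, dk, lig_mask)
  lig_att <- fwd_attention_dir(tp, le, pe, bp$attn_lq, cfg$attention_heads, dk, poc_mask)
  if (!all(poc_mask)) poc_att <- ad_mulc(tp, poc_att, matrix(as.numeric(poc_mask), length(poc_mask), h))
  if (!all(lig_mask)) lig_att <- ad_mulc(tp, lig_att, matrix(as.numeric(lig_mask), length(lig_mask), h))
  # pocket side: plain conv; ligand side: dilated stack, concatenated
  pc <- nn_conv1d_dilated(tp, poc_att, poc_mask, bp$poc_conv, 1L)
  louts <- integer(0)
  cur <- lig_att
  for (li in seq_along(cfg$ligand_dilations)) {
    cur <- nn_conv1d_dilated(tp, cur, lig_mask, bp$lig_conv[[li]], cfg$ligand_dilations[li])
    louts <- c(louts, cur)
  }
  lc <- nn_linear(tp, ad_masked_mean(tp, ad_cbind(tp, louts), lig_mask), bp$lig_proj)
  pvec <- ad_masked_mean(tp, pc, poc_mask)
  both <- ad_cbind(tp, c(pvec, lc))
  list(vec = nn_linear(tp, both, bp$out), poc_enriched = poc_att, lig_enriched = lig_att)
}

fwd_egnn <- function(tp, bp, g, cfg) {
  n <- nrow(g$node_features)
  h <- ad_relu(tp, nn_linear(tp, ad_const(tp, g$node_features), bp$embed))
  x <- ad_const(tp, g$coords)
  if (nrow(g$edges) > 0L) {
    ei <- c(g$edges[, 1L], g$edges[, 2L])
    ej <- c(g$edges[, 2L], g$edges[, 1L])
  } else {
    ei <- integer(0)
    ej <- integer(0)
  }
  deg <- tabulate(ei, nbins = n)
  invdeg <- matrix(1 / pmax(deg, 1L), ncol = 1L)
  pooled <- integer(0)
  for (ly in bp$layers) {
    if (length(ei) > 0L) {
      hi <- ad_gather(tp, h, ei)
      hj <- ad_gather(tp, h, ej)
      xi <- ad_gather(tp, x, ei)
      xj <- ad_gather(tp, x, ej)
      dx <- ad_sub(tp, xi, xj)
      d2 <- ad_rowsums(tp, ad_mul(tp, dx, dx))
      m <- nn_mlp2(tp, ad_cbind(tp, c(hi, hj, d2)), ly$msg1, ly$msg2)
      m <- ad_relu(tp, m)
      agg <- ad_mulc(tp, ad_segsum(tp, m, ei, n),
                     matrix(as.numeric(invdeg), n, ncol(ad_value(tp, m))))
      # coordinate update: equivariant relative-position weighting (tanh clamp)
      xw <- ad_tanh(tp, nn_linear(tp, m, ly$xw))
      dxw <- ad_mul_rows(tp, dx, xw)
      xagg <- ad_mulc(tp, ad_segsum(tp, dxw, ei, n), matrix(as.numeric(invdeg), n, 3L))
      x <- ad_add(tp, x, xagg)
    } else {
      agg <- ad_const(tp, matrix(0, n, cfg$hidden_dim))
    }
    upd <- nn_mlp2(tp, ad_cbind(tp, c(h, agg)), ly$upd1, ly$upd2)
    h <- ad_add(tp, h, upd)
    pooled <- c(pooled, ad_masked_mean(tp, h))
  }
  nn_linear(tp, ad_cbind(tp, pooled), bp$proj)
}

fwd_afp <- function(tp, bp, g, cfg) {
  n <- nrow(g$node_features)
  h <- ad_lrelu(tp, nn_linear(tp, ad_const(tp, g$node_features), bp$embed))
  ne <- nrow(g$edges)
  for (li in seq_along(bp$layers)) {
    ly <- bp$layers[[li]]
    if (ne > 0L) {
      src <- g$edges[, 1L]
      dst <- g$edges[, 2L]
      hs <- ad_gather(tp, h, src)
      hd <- ad_gather(tp, h, dst)
      inp <- if (li == 1L) {
        ad_cbind(tp, c(hd, hs, ad_const(tp, g$edge_features)))
      } else {
        ad_cbind(tp, c(hd, hs))
      }
      logits <- ad_lrelu(tp, nn_linear(tp, inp, ly$align))
      alpha <- ad_segsoftmax(tp, logits, dst, n)
      msg <- ad_relu(tp, nn_linear(tp, hs, ly$msg))
      ctx <- ad_segsum(tp, ad_mul_rows(tp, msg, alpha), dst, n)
    } else {
      ctx <- ad_const(tp, matrix(0, n, cfg$hidden_dim))
    }
    h <- nn_gru(tp, ctx, h, ly$gru)
  }
  # attentive super-node readout
  s <- ad_masked_mean(tp, h)
  ones <- rep(1L, n)
  for (t in seq_len(cfg$attentivefp_timesteps)) {
    srep <- ad_gather(tp, s, ones)
    logits <- ad_lrelu(tp, nn_linear(tp, ad_cbind(tp, c(srep, h)), bp$read_align))
    alpha <- ad_segsoftmax(tp, logits, ones, 1L)
    ctx <- ad_mm(tp, ad_t(tp, alpha), h)
    s <- nn_gru(tp, ctx, s, bp$read_gru)
  }
  s
}

fwd_hgt <- function(tp, bp, g, cfg, use_env = TRUE) {
  np <- nrow(g$protein_nodes)
  nl <- nrow(g$ligand_nodes)
  n <- np + nl
  hc <- ad_relu(tp, nn_linear(tp, ad_const(tp, rbind(g$protein_nodes, g$ligand_nodes)),
                              bp$c_embed))
  he <- if (use_env) {
    ad_relu(tp, nn_linear(tp, ad_const(tp, unclass(g$env_nodes)), bp$e_embed))
  } else NULL
  pl <- g$pl_edges
  if (nrow(pl) > 0L) {
    # directed both ways over the combined node indexing (ligand offset np)
    ei <- c(pl$p, pl$l + np)
    ej <- c(pl$l + np, pl$p)
    deg <- tabulate(ej, nbins = n)
    invdeg <- matrix(1 / pmax(deg, 1L), ncol = 1L)
  }
  ones_n <- rep(1L, n)
  for (ly in bp$layers) {
    if (use_env) {
      # Step 1: environment -> complex nodes (mean over the 3 env nodes)
      envmean <- ad_scale(tp, ad_colsums(tp, he), 1 / 3)
      nbr1 <- ad_gather(tp, envmean, ones_n)
      hc <- ad_relu(tp, ad_add(tp, nn_linear(tp, hc, ly$s1_self),
                               ad_mm(tp, nbr1, ly$s1_nbr)))
    }
    # Step 2: protein <-> ligand contacts (consumes Step 1's output)
    if (nrow(pl) > 0L) {
      msg <- ad_gather(tp, hc, ei)
      nbrsum <- ad_segsum(tp, msg, ej, n)
      nbr2 <- ad_mulc(tp, nbrsum, matrix(as.numeric(invdeg), n, cfg$hidden_dim))
    } else {
      nbr2 <- ad_const(tp, matrix(0, n, cfg$hidden_dim))
    }
    hc <- ad_relu(tp, ad_add(tp, nn_linear(tp, hc, ly$s2_self),
                             ad_mm(tp, nbr2, ly$s2_nbr)))
    if (use_env) {
      # Step 3: complex nodes -> environment
      cmean <- ad_masked_mean(tp, hc)
      nbr3 <- ad_gather(tp, cmean, c(1L, 1L, 1L))
      he <- ad_relu(tp, ad_add(tp, nn_linear(tp, he, ly$s3_self),
                               ad_mm(tp, nbr3, ly$s3_nbr)))
    }
  }
  # edge pooling: distance-gated mean over contact edges; falls back to
  # type-wise node means when no contact exists
  if (nrow(pl) > 0L) {
    hp <- ad_gather(tp, hc, pl$p)
    hl <- ad_gather(tp, hc, pl$l + np)
    states <- ad_cbind(tp, c(hp, hl))
    dcol <- ad_const(tp, matrix(pl$dist, ncol = 1L))
    w <- ad_sigmoid(tp, ad_bias(tp, ad_mm(tp, dcol, bp$edge_w$a),
                                bp$edge_w$b))
    pooled <- ad_scale(tp, ad_colsums(tp, ad_mul_rows(tp, states, w)), 1 / nrow(pl))
  } else {
    pmean <- ad_masked_mean(tp, hc, c(rep(TRUE, np), rep(FALSE, nl)))
    lmean <- ad_masked_mean(tp, hc, c(rep(FALSE, np), rep(TRUE, nl)))
    pooled <- ad_cbind(tp, c(pmean, lmean))
  }
  nn_mlp2(tp, pooled, bp$pool1, bp$pool2)
}

fwd_fusion <- function(tp, bp, branch_vecs) {
  x <- ad_cbind(tp, branch_vecs)
  x <- ad_relu(tp, nn_linear(tp, x, bp$l1))
  x <- ad_relu(tp, nn_linear(tp, x, bp$l2))
  nn_linear(tp, x, bp$l3)
}

# ---- featurization cache and full forward ----------------------------------

# crop a SequenceFeatureMatrix to its valid rows (padding is inert by
# construction, so this is a pure speed optimisation)
crop_seqfeat <- function(sf) {
  L <- sum(sf$mask)
  if (L == 0L) stop("all-masked sequence input")
  list(values = sf$values[seq_len(L), , drop = FALSE], mask = rep(TRUE, L))
}

#' Precompute every model input for a complex
#'
#' Featurization and graph construction are deterministic and reused across
#' training epochs; this bundles them once.
#'
#' @param record a `ComplexRecord`.
#' @param cfg a [model_config()].
#' @return list of encoder inputs (class `ComplexInputs`).
#' @export
prepare_complex_inputs <- function(record, cfg) {
  out <- list(complex_id = record$complex_id, label = record$affinity_label)
  sse <- paste(record$pocket_residues$sse, collapse = "")
  if (cfg$branches$protein) {
    out$pro <- crop_seqfeat(encode_protein_sequence(record$protein_seq))
  }
  if (cfg$branches$sequence_complex) {
    out$poc <- crop_seqfeat(encode_pocket_sequence(record$pocket_seq, sse))
    out$lig <- crop_seqfeat(encode_ligand_smiles(record$ligand))
  }
  if (cfg$branches$covalent) {
    out$pocket_graph <- build_pocket_graph(record)
    out$ligand_graph <- build_ligand_graph(record$ligand)
  }
  if (cfg$branches$noncovalent) {
    out$complex_graph <- build_complex_graph(record)
  }
  structure(out, class = "ComplexInputs")
}

# full forward pass; returns the scalar prediction node
forward_affinity <- function(tp, params, inputs, cfg) {
  vecs <- integer(0)
  if (cfg$branches$protein) {
    x <- ad_const(tp, inputs$pro$values)
    vecs <- c(vecs, fwd_protein(tp, params$protein, x, inputs$pro$mask,
                                cfg$protein_dilations))
  }
  if (cfg$branches$sequence_complex) {
    sc <- fwd_seqcplx(tp, params$seqcplx,
                      ad_const(tp, inputs$poc$values), inputs$poc$mask,
                      ad_const(tp, inputs$lig$values), inputs$lig$mask, cfg)
    vecs <- c(vecs, sc$vec)
  }
  if (cfg$branches$covalent) {
    vecs <- c(vecs, fwd_egnn(tp, params$egnn, inputs$pocket_graph, cfg))
    vecs <- c(vecs, fwd_afp(tp, params$afp, inputs$ligand_graph, cfg))
  }
  if (cfg$branches$noncovalent) {
    vecs <- c(vecs, fwd_hgt(tp, params$hgt, inputs$complex_graph, cfg,
                            use_env = cfg$branches$environment_nodes))
  }
  fwd_fusion(tp, params$fusion, vecs)
}

# ---- exported inference ops ------------------------------------------------

#' Encode a padded sequence matrix with the dilated-convolution stack
#'
#' Five (by default) masked 1-D convolutions with increasing dilation,
#' concatenated across layers and mask-mean-pooled to a fixed-width vector.
#' Output is independent of the amount of trailing padding.
#'
#' @param x a `SequenceFeatureMatrix` of kind `"protein"` (or anything with
#'   40 feature columns).
#' @param params model parameters from [init_model_params()].
#' @param cfg the matching [model_config()].
#' @param dilations dilation schedule (default `cfg$protein_dilations`).
#' @return numeric vector of length `cfg$hidden_dim`.
#' @export
dilated_conv_encode <- function(x, params, cfg, dilations = cfg$protein_dilations) {
  cr <- crop_seqfeat(x)
  tp <- ad_tape()
  bp <- bind_params(tp, params$protein)
  out <- fwd_protein(tp, bp, ad_const(tp, cr$values), cr$mask, dilations)
  as.numeric(ad_value(tp, out))
}

#' Bidirectional pocket-ligand cross-attention
#'
#' Two-head scaled dot-product attention, first with the pocket as query and
#' the ligand as key/value, then the reverse; padded key positions receive
#' zero attention weight.
#'
#' @param poc pocket `SequenceFeatureMatrix`.
#' @param lig ligand `SequenceFeatureMatrix`.
#' @param params model parameters.
#' @param cfg the matching [model_config()].
#' @return list with `poc_enriched` and `lig_enriched` matrices (valid rows
#'   only) and `attn_poc`/`attn_lig` attention-weight matrices.
#' @export
cross_attention <- function(poc, lig, params, cfg) {
  pc <- crop_seqfeat(poc)
  lc <- crop_seqfeat(lig)
  tp <- ad_tape()
  bp <- bind_params(tp, params$seqcplx)
  h <- cfg$hidden_dim
  pe <- ad_relu(tp, nn_linear(tp, ad_const(tp, pc$values), bp$poc_embed))
  le <- ad_relu(tp, nn_linear(tp, ad_const(tp, lc$values), bp$lig_embed))
  poc_att <- fwd_attention_dir(tp, pe, le, bp$attn_pq, cfg$attention_heads,
                               cfg$key_dim, lc$mask)
  lig_att <- fwd_attention_dir(tp, le, pe, bp$attn_lq, cfg$attention_heads,
                               cfg$key_dim, pc$mask)
  # single-head attention maps for inspection
  aw <- function(q_in, kv_in, ap, kmask) {
    Q <- ad_mm(tp, q_in, ap$Wq)
    K <- ad_mm(tp, kv_in, ap$Wk)
    cols <- seq_len(cfg$key_dim)
    sc <- ad_scale(tp, ad_mm(tp, ad_mulc_cols(tp, Q, cols),
                             ad_t(tp, ad_mulc_cols(tp, K, cols))),
                   1 / sqrt(cfg$key_dim))
    ad_value(tp, ad_softmax_rows(tp, sc, kmask))
  }
  list(poc_enriched = ad_value(tp, poc_att),
       lig_enriched = ad_value(tp, lig_att),
       attn_poc = aw(pe, le, bp$attn_pq, lc$mask),
       attn_lig = aw(le, pe, bp$attn_lq, pc$mask))
}

#' Encode a pocket graph with the E(n)-invariant encoder
#'
#' Three message-passing layers whose messages depend on squared
#' inter-residue distances only; per-layer node states are concatenated and
#' pooled, so the output is invariant to rigid motions of the coordinates
#' and to node relabelling.
#'
#' @param g a `PocketGraph`.
#' @param params model parameters.
#' @param cfg the matching [model_config()].
#' @return numeric vector of length `cfg$hidden_dim` (the pocket 3-D branch
#'   embedding).
#' @export
egnn_encode <- function(g, params, cfg) {
  stopifnot(inherits(g, "PocketGraph"))
  if (nrow(g$node_features) == 0L) stop("empty pocket graph")
  tp <- ad_tape()
  bp <- bind_params(tp, params$egnn)
  as.numeric(ad_value(tp, fwd_egnn(tp, bp, g, cfg)))
}

#' Encode a ligand graph with the attentive-fingerprint encoder
#'
#' Graph-attention atom updates with a GRU state over
#' `cfg$attentivefp_layers` rounds, then an attentive molecule-level readout
#' over `cfg$attentivefp_timesteps` timesteps.
#'
#' @param g a `LigandGraph`.
#' @param params model parameters.
#' @param cfg the matching [model_config()].
#' @return numeric vector of length `cfg$hidden_dim`.
#' @export
attentivefp_encode <- function(g, params, cfg) {
  stopifnot(inherits(g, "LigandGraph"))
  if (nrow(g$node_features) == 0L) stop("empty ligand graph")
  tp <- ad_tape()
  bp <- bind_params(tp, params$afp)
  as.numeric(ad_value(tp, fwd_afp(tp, bp, g, cfg)))
}

#' Encode a complex graph with the three-step environment-aware scheme
#'
#' Per layer, strictly in order: (1) SAGE update of protein/ligand nodes
#' from the environment nodes, (2) SAGE update over the bidirectional
#' protein-ligand contact relation (consuming step 1's output), (3) SAGE
#' update of the environment nodes from the protein/ligand nodes. Follows
#' with distance-gated edge pooling and an MLP. With
#' `cfg$branches$environment_nodes = FALSE` steps 1 and 3 are skipped.
#'
#' @param g a `ComplexGraph`.
#' @param params model parameters.
#' @param cfg the matching [model_config()].
#' @return numeric vector of length `cfg$hidden_dim`.
#' @export
env_hgt_encode <- function(g, params, cfg) {
  stopifnot(inherits(g, "ComplexGraph"))
  tp <- ad_tape()
  bp <- bind_params(tp, params$hgt)
  as.numeric(ad_value(tp, fwd_hgt(tp, bp, g, cfg,
                                  use_env = cfg$branches$environment_nodes)))
}

#' Predict the binding affinity of one complex
#'
#' Runs every enabled branch and the fusion MLP. Deterministic given
#' `(record, cfg, params)`.
#'
#' @param record a `ComplexRecord` (or precomputed `ComplexInputs`).
#' @param cfg a [model_config()].
#' @param params parameters from [init_model_params()] or training.
#' @return scalar predicted affinity (-log10 Kd/Ki).
#' @export
predict_affinity <- function(record, cfg, params) {
  inputs <- if (inherits(record, "ComplexInputs")) record else {
    prepare_complex_inputs(record, cfg)
  }
  tp <- ad_tape()
  bp <- bind_params(tp, params)
  as.numeric(ad_value(tp, forward_affinity(tp, bp, inputs, cfg)))
}

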