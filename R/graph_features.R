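# Sub-structure graphs and a three-layer graph-attention encoder with
# mean||max aggregation, trained with a linear softmax head and Adam, all in
# base R (graphs are small: tens of nodes, 42-dim features).

#' Build the sub-structure graph of a protein
#'
#' Nodes are compact sub-structures (mean window distance < 10 Angstrom,
#' from [extract_substructures()]); node features are the 42-dim surface
#' chemistry layout computed on the covered residues (20 AAC + 22 property
#' expectations); an edge joins two nodes whose centroids (mean CA
#' coordinate of the covered residues) are closer than `edge_dist`.
#'
#' @param p a `protein_structure`.
#' @param sub_threshold compactness cutoff for node selection (default 10).
#' @param edge_dist centroid distance cutoff for edges (default 10).
#' @param properties property table for the node features.
#' @return object of class `protein_graph`: list with `features` (n x 42),
#'   `edges` (2-column matrix of node indices, u < v), `centroids` (n x 3).
#' @export
build_graph <- function(p, sub_threshold = 10, edge_dist = 10,
                        properties = default_property_table()) {
  subs <- extract_substructures(p, threshold = sub_threshold)
  n <- nrow(subs$reps)
  if (n == 0L) {
    return(structure(list(features = matrix(numeric(0), 0, 42),
                          edges = matrix(integer(0), 0, 2),
                          centroids = matrix(numeric(0), 0, 3)),
                     class = "protein_graph"))
  }
  window <- 10L
  feats <- matrix(0, n, 20L + ncol(properties))
  for (r in seq_len(n)) {
    i <- subs$windows$row_off[r]
    j <- subs$windows$col_off[r]
    covered <- sort(unique(c((i + 1L):(i + window), (j + 1L):(j + window))))
    aa <- p$residues$aa[covered]
    aa <- aa[aa %in% AA20]
    if (length(aa)) {
      alpha <- as.numeric(table(factor(aa, levels = AA20))) / length(aa)
      feats[r, seq_len(20L)] <- alpha
      feats[r, 20L + seq_len(ncol(properties))] <- as.numeric(alpha %*% properties)
    }
  }
  colnames(feats) <- c(paste0("aac_", AA20), colnames(properties))
  if (n > 1L) {
    dc <- as.matrix(dist(subs$centroids))
    idx <- which(upper.tri(dc) & dc < edge_dist, arr.ind = TRUE)
    edges <- unname(cbind(idx[, 1], idx[, 2]))
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  structure(list(features = feats, edges = edges,
                 centroids = subs$centroids),
            class = "protein_graph")
}

# Xavier-style initialization of one attention layer: W (d_out x d_in) and
# attention vector u (2 * d_out).
init_gat_params <- function(d_in = 42L, d_out = 42L, n_layers = 3L) {
  lapply(seq_len(n_layers), function(l) {
    din <- if (l == 1L) d_in else d_out
    list(W = matrix(rnorm(d_out * din, sd = sqrt(2 / (din + d_out))),
                    d_out, din),
         u = rnorm(2L * d_out, sd = sqrt(1 / d_out)))
  })
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
relu <- function(x) pmax(x, 0)

# softmax rows of a matrix with -Inf masking
row_softmax <- function(s) {
  s <- s - apply(s, 1, max)
  e <- exp(s)
  e[is.na(e)] <- 0
  e / rowSums(e)
}

# one attention layer: scores e_ij = leakyrelu(u . [Wh_i || Wh_j]) over
# N_i U {i}, softmax-normalized, output relu(sum_j a_ij W h_j).
gat_layer <- function(h, edges, params, return_attention = FALSE) {
  n <- nrow(h)
  Wh <- h %*% t(params$W) # n x d_out
  d_out <- ncol(Wh)
  u1 <- params$u[seq_len(d_out)]
  u2 <- params$u[d_out + seq_len(d_out)]
  s1 <- as.numeric(Wh %*% u1)
  s2 <- as.numeric(Wh %*% u2)
  adj <- diag(n) > 0
  if (nrow(edges)) {
    adj[edges] <- TRUE
    adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  scores <- outer(s1, s2, "+")
  scores <- leaky_relu(scores)
  scores[!adj] <- -Inf
  att <- row_softmax(scores)
  out <- relu(att %*% Wh)
  if (return_attention) list(h = out, attention = att) else list(h = out)
}

#' Forward pass of the graph-attention encoder
#'
#' Three attention layers (widths 42/42/42) followed by mean and
#' per-dimension max aggregation over nodes, concatenated to 84 values.
#'
#' @param g a `protein_graph`.
#' @param params list of 3 layers from [init_gat_params()] or [train_gat()].
#' @param return_attention also return per-layer attention matrices.
#' @return named numeric vector of length 84 (attributes carry attention
#'   when requested).
#' @export
gat_forward <- function(g, params, return_attention = FALSE) {
  n <- nrow(g$features)
  if (n == 0L) {
    warning("empty graph; zero representation")
    v <- numeric(84L)
    names(v) <- c(paste0("avg_", 1:42), paste0("max_", 1:42))
    return(v)
  }
  h <- g$features
  atts <- list()
  for (l in seq_along(params)) {
    step <- gat_layer(h, g$edges, params[[l]], return_attention)
    h <- step$h
    if (return_attention) atts[[l]] <- step$attention
  }
  v <- c(colMeans(h), apply(h, 2, max))
  names(v) <- c(paste0("avg_", 1:42), paste0("max_", 1:42))
  if (return_attention) attr(v, "attention") <- atts
  v
}

# numerically stable log-softmax cross-entropy and its gradient wrt logits
softmax_xent <- function(logits, y_onehot) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  list(loss = -sum(y_onehot * (z - log(sum(exp(z))))), grad = p - y_onehot)
}

#' Train the graph-attention encoder
#'
#' Appends a linear softmax classification head to the 84-dim aggregation
#' output and minimizes cross-entropy with Adam; gradients for the head and
#' all three attention layers come from full analytic backpropagation.
#' After training the head is discarded and the 84-dim aggregation output
#' is the descriptor.
#'
#' @param graphs list of `protein_graph`.
#' @param labels factor or character vector of class labels.
#' @param epochs training epochs (default 300).
#' @param lr Adam learning rate (default 5e-3).
#' @param seed RNG seed for initialization and any shuffling.
#' @param d_hidden layer width (42 so that mean||max is 84).
#' @return list with `params` (3 attention layers), `classes`, `loss_trace`.
#' @export
train_gat <- function(graphs, labels, epochs = 300L, lr = 5e-3, seed = 1L,
                      d_hidden = 42L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need >= 2 classes")
  classes <- levels(droplevels(labels))
  y <- as.integer(droplevels(labels))
  set.seed(seed)
  d_in <- ncol(graphs[[1]]$features)
  params <- init_gat_params(d_in, d_hidden)
  K <- length(classes)
  head_W <- matrix(rnorm(K * 2 * d_hidden, sd = 0.05), K, 2 * d_hidden)
  head_b <- numeric(K)

  theta <- flatten_params(params, head_W, head_b)
  adam_m <- numeric(length(theta))
  adam_v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    gr <- numeric(length(theta))
    total <- 0
    pk <- unflatten_params(theta, d_in, d_hidden, K)
    for (gi in seq_along(graphs)) {
      res <- gat_grad(graphs[[gi]], pk$params, pk$head_W, pk$head_b, y[gi], K)
      total <- total + res$loss
      gr <- gr + res$grad
    }
    gr <- gr / length(graphs)
    total <- total / length(graphs)
    loss_trace[ep] <- total
    adam_m <- b1 * adam_m + (1 - b1) * gr
    adam_v <- b2 * adam_v + (1 - b2) * gr^2
    mhat <- adam_m / (1 - b1^ep)
    vhat <- adam_v / (1 - b2^ep)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  }
  pk <- unflatten_params(theta, d_in, d_hidden, K)
  list(params = pk$params, classes = classes, loss_trace = loss_trace,
       head = list(W = pk$head_W, b = pk$head_b))
}

flatten_params <- function(params, head_W, head_b) {
  c(unlist(lapply(params, function(p) c(as.numeric(p$W), p$u))),
    as.numeric(head_W), head_b)
}

unflatten_params <- function(theta, d_in, d_h, K) {
  params <- list()
  off <- 0L
  for (l in 1:3) {
    din <- if (l == 1L) d_in else d_h
    nw <- d_h * din
    W <- matrix(theta[off + seq_len(nw)], d_h, din)
    off <- off + nw
    u <- theta[off + seq_len(2L * d_h)]
    off <- off + 2L * d_h
    params[[l]] <- list(W = W, u = u)
  }
  nw <- K * 2L * d_h
  head_W <- matrix(theta[off + seq_len(nw)], K, 2L * d_h)
  off <- off + nw
  head_b <- theta[off + seq_len(K)]
  list(params = params, head_W = head_W, head_b = head_b)
}

# forward + backward for one graph; returns loss and flattened gradient.
gat_grad <- function(g, params, head_W, head_b, y, K) {
  n <- nrow(g$features)
  d_h <- nrow(params[[1]]$W)
  if (n == 0L) {
    return(list(loss = 0, grad = numeric(length(
      flatten_params(params, head_W, head_b)))))
  }
  # ---- forward, caching intermediates
  hs <- list(g$features)
  cache <- list()
  for (l in seq_along(params)) {
    h <- hs[[l]]
    W <- params[[l]]$W
    u <- params[[l]]$u
    Wh <- h %*% t(W)
    d_out <- ncol(Wh)
    u1 <- u[seq_len(d_out)]
    u2 <- u[d_out + seq_len(d_out)]
    s1 <- as.numeric(Wh %*% u1)
    s2 <- as.numeric(Wh %*% u2)
    adj <- diag(n) > 0
    if (nrow(g$edges)) {
      adj[g$edges] <- TRUE
      adj[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
    }
    raw <- outer(s1, s2, "+")
    lrelu <- leaky_relu(raw)
    lrelu[!adj] <- -Inf
    att <- row_softmax(lrelu)
    pre <- att %*% Wh
    act <- relu(pre)
    cache[[l]] <- list(Wh = Wh, s1 = s1, s2 = s2, adj = adj, raw = raw,
                       att = att, pre = pre)
    hs[[l + 1L]] <- act
  }
  hf <- hs[[length(hs)]]
  avg <- colMeans(hf)
  mx <- apply(hf, 2, max)
  argmx <- max.col(t(hf), ties.method = "first")
  z <- c(avg, mx)
  logits <- as.numeric(head_W %*% z + head_b)
  yh <- numeric(K)
  yh[y] <- 1
  sx <- softmax_xent(logits, yh)

  # ---- backward
  g_headW <- outer(sx$grad, z)
  g_headb <- sx$grad
  g_z <- as.numeric(t(head_W) %*% sx$grad)
  g_avg <- g_z[seq_len(d_h)]
  g_max <- g_z[d_h + seq_len(d_h)]
  g_h <- matrix(rep(g_avg / n, each = n), n, d_h)
  for (k in seq_len(d_h)) {
    g_h[argmx[k], k] <- g_h[argmx[k], k] + g_max[k]
  }
  g_params <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    cc <- cache[[l]]
    h_in <- hs[[l]]
    W <- params[[l]]$W
    d_out <- nrow(W)
    u1 <- params[[l]]$u[seq_len(d_out)]
    u2 <- params[[l]]$u[d_out + seq_len(d_out)]
    g_pre <- g_h * (cc$pre > 0)
    g_att <- g_pre %*% t(cc$Wh)        # n x n
    g_Wh_from_mix <- t(cc$att) %*% g_pre # n x d_out
    # softmax backward per row
    g_lrelu <- cc$att * (g_att - rowSums(g_att * cc$att))
    g_raw <- g_lrelu * ifelse(cc$raw > 0, 1, 0.2)
    g_raw[!cc$adj] <- 0
    g_s1 <- rowSums(g_raw)
    g_s2 <- colSums(g_raw)
    g_Wh <- g_Wh_from_mix + outer(g_s1, u1) + outer(g_s2, u2)
    g_u1 <- as.numeric(t(cc$Wh) %*% g_s1)
    g_u2 <- as.numeric(t(cc$Wh) %*% g_s2)
    g_W <- t(g_Wh) %*% h_in
    g_h <- g_Wh %*% W
    g_params[[l]] <- list(W = g_W, u = c(g_u1, g_u2))
  }
  list(loss = sx$loss,
       grad = c(unlist(lapply(g_params, function(p) c(as.numeric(p$W), p$u))),
                as.numeric(g_headW), g_headb))
}
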