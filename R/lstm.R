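# Stacked (optionally bidirectional) LSTM regression network in base R:
# linear embedding -> LSTM stack -> dense head on the final hidden state.
# Training is full backpropagation-through-time with Adam and early
# stopping; gradients are verified against finite differences in the test
# suite. Gate layout in the fused weight matrices is [input | forget |
# output | candidate].

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

new_lstm_cell <- function(input_dim, units) {
  b <- rep(0, 4 * units)
  b[(units + 1):(2 * units)] <- 1        # forget-gate bias init
  list(W = glorot(input_dim, 4 * units), U = glorot(units, 4 * units), b = b,
       units = units, input_dim = input_dim)
}

#' Construct an LSTM regression network
#'
#' Architecture: linear embedding (`input_dim -> embed_dim`), a stack of
#' LSTM layers (each optionally bidirectional, in which case its output is
#' the concatenation of the forward- and reverse-time hidden sequences),
#' and a linear head on the final layer's last hidden state. Dropout
#' (inverted) is applied to the embedding and to every non-final LSTM
#' layer's output during training.
#'
#' @param input_dim Number of input features per time step.
#' @param embed_dim Embedding width.
#' @param layers List of layer specs `list(units =, bidirectional =)`.
#' @param output_dim Number of regression outputs.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param seed Seed for weight initialisation.
#' @return An `lstm_net` object (parameters + architecture).
#' @export
lstm_net <- function(input_dim, embed_dim = 16,
                     layers = list(list(units = 16, bidirectional = FALSE),
                                   list(units = 16, bidirectional = TRUE),
                                   list(units = 8, bidirectional = FALSE)),
                     output_dim = 1, dropout = 0.3, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1)
  set.seed(seed)
  cells <- list()
  in_dim <- embed_dim
  for (l in seq_along(layers)) {
    spec <- layers[[l]]
    cells[[l]] <- list(
      fwd = new_lstm_cell(in_dim, spec$units),
      bwd = if (isTRUE(spec$bidirectional)) new_lstm_cell(in_dim, spec$units),
      bidirectional = isTRUE(spec$bidirectional))
    in_dim <- spec$units * (1 + isTRUE(spec$bidirectional))
  }
  structure(list(
    We = glorot(input_dim, embed_dim), be = rep(0, embed_dim),
    cells = cells,
    Wo = glorot(in_dim, output_dim), bo = rep(0, output_dim),
    input_dim = input_dim, embed_dim = embed_dim, output_dim = output_dim,
    hidden_dim = in_dim, dropout = dropout), class = "lstm_net")
}

# One direction of an LSTM layer over a (B, T, in_dim) sequence stored as a
# list of B x in_dim matrices. Returns hidden states and the caches needed
# for BPTT.
lstm_forward_dir <- function(cell, xs, reverse = FALSE) {
  tt <- length(xs)
  b <- nrow(xs[[1]])
  h <- matrix(0, b, cell$units)
  cstate <- matrix(0, b, cell$units)
  order_t <- if (reverse) tt:1 else 1:tt
  hs <- vector("list", tt)
  cache <- vector("list", tt)
  for (t in order_t) {
    z <- xs[[t]] %*% cell$W + h %*% cell$U +
      matrix(cell$b, b, 4 * cell$units, byrow = TRUE)
    u <- cell$units
    i <- sigmoid(z[, 1:u, drop = FALSE])
    f <- sigmoid(z[, (u + 1):(2 * u), drop = FALSE])
    o <- sigmoid(z[, (2 * u + 1):(3 * u), drop = FALSE])
    g <- tanh(z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cstate
    cstate <- f * c_prev + i * g
    tc <- tanh(cstate)
    h_prev <- h
    h <- o * tc
    hs[[t]] <- h
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c = cstate,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(hs = hs, cache = cache, order_t = order_t)
}

lstm_backward_dir <- function(cell, xs, fw, dhs) {
  tt <- length(xs)
  b <- nrow(xs[[1]])
  u <- cell$units
  dW <- matrix(0, nrow(cell$W), ncol(cell$W))
  dU <- matrix(0, u, 4 * u)
  db <- rep(0, 4 * u)
  dxs <- lapply(xs, function(x) matrix(0, b, ncol(x)))
  dh_carry <- matrix(0, b, u)
  dc_carry <- matrix(0, b, u)
  for (t in rev(fw$order_t)) {
    ca <- fw$cache[[t]]
    dh <- dhs[[t]] + dh_carry
    dc <- dh * ca$o * (1 - ca$tc^2) + dc_carry
    dzo <- dh * ca$tc * ca$o * (1 - ca$o)
    dzi <- dc * ca$g * ca$i * (1 - ca$i)
    dzf <- dc * ca$c_prev * ca$f * (1 - ca$f)
    dzg <- dc * ca$i * (1 - ca$g^2)
    dz <- cbind(dzi, dzf, dzo, dzg)
    dW <- dW + crossprod(xs[[t]], dz)
    dU <- dU + crossprod(ca$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dxs[[t]] + dz %*% t(cell$W)
    dh_carry <- dz %*% t(cell$U)
    dc_carry <- dc * ca$f
  }
  list(dW = dW, dU = dU, db = db, dxs = dxs)
}

# Full forward pass. X is a (B, T, D) array; returns predictions, the final
# representation, and (when training) all caches and dropout masks.
lstm_forward <- function(net, x, training = FALSE) {
  b <- dim(x)[1]; tt <- dim(x)[2]
  xs <- lapply(seq_len(tt), function(t)
    matrix(x[, t, ], b, net$input_dim) %*% net$We +
      matrix(net$be, b, net$embed_dim, byrow = TRUE))
  masks <- list()
  drop_layer <- function(hs, key) {
    if (!training || net$dropout == 0) return(hs)
    keep <- 1 - net$dropout
    m <- lapply(hs, function(h)
      matrix(stats::rbinom(length(h), 1, keep) / keep, nrow(h), ncol(h)))
    masks[[key]] <<- m
    Map(`*`, hs, m)
  }
  xs <- drop_layer(xs, "embed")
  layer_io <- list()
  cur <- xs
  for (l in seq_along(net$cells)) {
    cl <- net$cells[[l]]
    fwd <- lstm_forward_dir(cl$fwd, cur, reverse = FALSE)
    if (cl$bidirectional) {
      bwd <- lstm_forward_dir(cl$bwd, cur, reverse = TRUE)
      hs <- Map(cbind, fwd$hs, bwd$hs)
    } else {
      bwd <- NULL
      hs <- fwd$hs
    }
    layer_io[[l]] <- list(input = cur, fwd = fwd, bwd = bwd)
    if (l < length(net$cells)) hs <- drop_layer(hs, paste0("layer", l))
    cur <- hs
  }
  h_repr <- cur[[tt]]
  yhat <- h_repr %*% net$Wo + matrix(net$bo, b, net$output_dim, byrow = TRUE)
  list(yhat = yhat, h_repr = h_repr, xs_embed = xs, layer_io = layer_io,
       final_hs = cur, masks = masks, x = x)
}

# Backward pass for mean-squared-error loss; returns gradients for every
# parameter matrix in the net.
lstm_backward <- function(net, fw, y) {
  b <- nrow(fw$yhat); tt <- length(fw$final_hs)
  dyhat <- 2 * (fw$yhat - y) / length(y)
  grads <- list(
    dWo = crossprod(fw$h_repr, dyhat), dbo = colSums(dyhat))
  dh_final <- dyhat %*% t(net$Wo)
  dhs <- lapply(fw$final_hs, function(h) matrix(0, b, ncol(h)))
  dhs[[tt]] <- dh_final
  for (l in rev(seq_along(net$cells))) {
    cl <- net$cells[[l]]
    io <- fw$layer_io[[l]]
    if (l < length(net$cells) && !is.null(fw$masks[[paste0("layer", l)]])) {
      dhs <- Map(`*`, dhs, fw$masks[[paste0("layer", l)]])
    }
    u <- cl$fwd$units
    if (cl$bidirectional) {
      d_fwd <- lapply(dhs, function(d) d[, 1:u, drop = FALSE])
      d_bwd <- lapply(dhs, function(d) d[, (u + 1):(2 * u), drop = FALSE])
      g_f <- lstm_backward_dir(cl$fwd, io$input, io$fwd, d_fwd)
      g_b <- lstm_backward_dir(cl$bwd, io$input, io$bwd, d_bwd)
      grads[[paste0("l", l, "_fwd")]] <- g_f[c("dW", "dU", "db")]
      grads[[paste0("l", l, "_bwd")]] <- g_b[c("dW", "dU", "db")]
      dhs <- Map(`+`, g_f$dxs, g_b$dxs)
    } else {
      g_f <- lstm_backward_dir(cl$fwd, io$input, io$fwd, dhs)
      grads[[paste0("l", l, "_fwd")]] <- g_f[c("dW", "dU", "db")]
      dhs <- g_f$dxs
    }
  }
  if (!is.null(fw$masks$embed)) dhs <- Map(`*`, dhs, fw$masks$embed)
  dWe <- matrix(0, nrow(net$We), ncol(net$We))
  dbe <- rep(0, ncol(net$We))
  for (t in seq_len(tt)) {
    xt <- matrix(fw$x[, t, ], b, net$input_dim)
    dWe <- dWe + crossprod(xt, dhs[[t]])
    dbe <- dbe + colSums(dhs[[t]])
  }
  grads$dWe <- dWe
  grads$dbe <- dbe
  grads
}

# Flatten parameters <-> update with Adam. Parameters are addressed by
# (path) accessor pairs so the optimiser state lines up across steps.
lstm_param_refs <- function(net) {
  refs <- list(list(get = function(n) n$We, set = function(n, v) { n$We <- v; n }),
               list(get = function(n) n$be, set = function(n, v) { n$be <- v; n }),
               list(get = function(n) n$Wo, set = function(n, v) { n$Wo <- v; n }),
               list(get = function(n) n$bo, set = function(n, v) { n$bo <- v; n }))
  grad_names <- c("dWe", "dbe", "dWo", "dbo")
  for (l in seq_along(net$cells)) {
    for (dir in c("fwd", "bwd")) {
      if (dir == "bwd" && !net$cells[[l]]$bidirectional) next
      for (p in c("W", "U", "b")) {
        local({
          ll <- l; dd <- dir; pp <- p
          refs[[length(refs) + 1]] <<- list(
            get = function(n) n$cells[[ll]][[dd]][[pp]],
            set = function(n, v) { n$cells[[ll]][[dd]][[pp]] <- v; n })
        })
        grad_names <- c(grad_names, paste0("l", l, "_", dir, "_", p))
      }
    }
  }
  list(refs = refs, grad_names = grad_names)
}

lstm_collect_grads <- function(grads, grad_names) {
  lapply(grad_names, function(nm) {
    if (nm %in% c("dWe", "dbe", "dWo", "dbo")) return(grads[[nm]])
    parts <- strsplit(nm, "_")[[1]]       # l<k> dir W/U/b
    grads[[paste0(parts[1], "_", parts[2])]][[paste0("d", parts[3])]]
  })
}

#' Train an LSTM network with Adam and early stopping
#'
#' Minimises mean squared error over mini-batches; training stops when the
#' validation loss has not improved for `patience` consecutive epochs (the
#' best-validation parameters are kept). Seeded runs are reproducible.
#'
#' @param net An [lstm_net()].
#' @param x `(B, T, D)` input array; `y` a `B x output_dim` matrix.
#' @param x_val,y_val Optional validation set (defaults to the training
#'   set, i.e. plain loss-plateau stopping).
#' @param learning_rate,batch_size,max_epochs Training hyperparameters.
#' @param adam_betas Adam `(beta1, beta2)`.
#' @param patience Early-stopping patience in epochs.
#' @param seed Seed for shuffling and dropout.
#' @return The trained net with a `history` element (per-epoch training and
#'   validation loss, epochs run, best epoch).
#' @export
fit_lstm <- function(net, x, y, x_val = NULL, y_val = NULL,
                     learning_rate = 0.001, batch_size = 32,
                     max_epochs = 100, adam_betas = c(0.9, 0.999),
                     patience = 10, seed = 1L) {
  y <- as.matrix(y)
  stopifnot(dim(x)[1] == nrow(y), patience <= max_epochs)
  if (is.null(x_val)) { x_val <- x; y_val <- y }
  y_val <- as.matrix(y_val)
  if (all(net$bo == 0)) net$bo <- colMeans(y)   # start at the target mean
  set.seed(seed)
  pr <- lstm_param_refs(net)
  m_state <- lapply(pr$refs, function(r) r$get(net) * 0)
  v_state <- m_state
  b1 <- adam_betas[1]; b2 <- adam_betas[2]; eps <- 1e-8
  step <- 0
  n <- dim(x)[1]
  best_val <- Inf; best_net <- net; best_epoch <- 0; stall <- 0
  hist_train <- hist_val <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    ep_loss <- 0
    for (bidx in batches) {
      xb <- x[bidx, , , drop = FALSE]
      yb <- y[bidx, , drop = FALSE]
      fw <- lstm_forward(net, xb, training = TRUE)
      batch_loss <- sum((fw$yhat - yb)^2)
      if (!is.finite(batch_loss)) {
        stop("fit_lstm: non-finite loss at epoch ", epoch,
             " (NaN targets or exploding gradients); check the inputs or ",
             "lower the learning rate", call. = FALSE)
      }
      ep_loss <- ep_loss + batch_loss
      grads <- lstm_backward(net, fw, yb)
      gl <- lstm_collect_grads(grads, pr$grad_names)
      step <- step + 1
      for (k in seq_along(pr$refs)) {
        g <- gl[[k]]
        m_state[[k]] <- b1 * m_state[[k]] + (1 - b1) * g
        v_state[[k]] <- b2 * v_state[[k]] + (1 - b2) * g^2
        mhat <- m_state[[k]] / (1 - b1^step)
        vhat <- v_state[[k]] / (1 - b2^step)
        net <- pr$refs[[k]]$set(net, pr$refs[[k]]$get(net) -
                                  learning_rate * mhat / (sqrt(vhat) + eps))
      }
    }
    hist_train <- c(hist_train, ep_loss / length(y))
    val_pred <- lstm_forward(net, x_val, training = FALSE)$yhat
    val_loss <- mean((val_pred - y_val)^2)
    hist_val <- c(hist_val, val_loss)
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_net <- net; best_epoch <- epoch; stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  best_net$history <- list(train_loss = hist_train, val_loss = hist_val,
                           epochs_run = length(hist_train),
                           best_epoch = best_epoch, best_val_loss = best_val)
  best_net
}

#' Predict from a trained LSTM network
#'
#' @param net A trained [lstm_net()].
#' @param x `(B, T, D)` input array.
#' @param representation Return the final hidden representation instead of
#'   the head output.
#' @return `B x output_dim` prediction matrix (or `B x hidden_dim`
#'   representation).
#' @export
predict_lstm <- function(net, x, representation = FALSE) {
  fw <- lstm_forward(net, x, training = FALSE)
  if (representation) fw$h_repr else fw$yhat
}
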