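# A small character-level autoregressive model: a fixed-context MLP
# ("neural n-gram") with a trainable character embedding, one tanh hidden
# layer, and a softmax over the character set. It exists to exercise the
# train -> memorize -> evaluate loop of the completion-model contract at desk
# scale; it makes no claim of generalizing to unseen synonyms the way a
# large pretrained model can.

lm_default_charset <- function() {
  c("",                       # index 1: pad / unknown
    letters, LETTERS, as.character(0:9),
    " ", ":", "-", ",", ".", "'", "(", ")")
}

encode_chars <- function(text, charset) {
  idx <- match(strsplit(text, "")[[1]], charset)
  idx[is.na(idx)] <- 1L
  idx
}

#' Create a small character-level completion model
#'
#' The model predicts each character from a fixed-length window of preceding
#' characters (padded on the left). The window must be long enough to reach
#' back from the identifier digits to the distinguishing words of the term —
#' in the training template about 37 characters separate the end of the term
#' from the first digit — hence the 64-character default. Parameter count at
#' the defaults is about 1.6e5, well under a million.
#'
#' @param context_len Context window length in characters (default 64).
#' @param embed_dim Character embedding dimension (default 12).
#' @param hidden_dim Hidden-layer width (default 256).
#' @param charset Character inventory; unknown characters map to the pad
#'   symbol.
#' @param seed Seed for random initialization.
#' @return An object of classes `char_lm`, `completion_model`.
#' @export
char_lm <- function(context_len = 64L, embed_dim = 12L, hidden_dim = 256L,
                    charset = lm_default_charset(), seed = 1L) {
  stopifnot(context_len >= 1, embed_dim >= 1, hidden_dim >= 1)
  V <- length(charset)
  d_in <- context_len * embed_dim
  params <- with_seed(seed, list(
    emb = matrix(stats::rnorm(V * embed_dim, sd = 0.1), V, embed_dim),
    W1 = matrix(stats::rnorm(d_in * hidden_dim, sd = sqrt(1 / d_in)),
                d_in, hidden_dim),
    b1 = rep(0, hidden_dim),
    W2 = matrix(stats::rnorm(hidden_dim * V, sd = sqrt(1 / hidden_dim)),
                hidden_dim, V),
    b2 = rep(0, V)
  ))
  structure(
    list(params = params, charset = charset,
         context_len = as.integer(context_len),
         embed_dim = as.integer(embed_dim),
         hidden_dim = as.integer(hidden_dim),
         n_params = V * embed_dim + d_in * hidden_dim + hidden_dim +
           hidden_dim * V + V,
         init_seed = as.integer(seed)),
    class = c("char_lm", "completion_model")
  )
}

#' @export
print.char_lm <- function(x, ...) {
  cat(sprintf("<char_lm> context=%d embed=%d hidden=%d (%s parameters)\n",
              x$context_len, x$embed_dim, x$hidden_dim,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# Stack (context window, target) examples for every character position of
# every text. Returns idx: n x context_len integer matrix, y: length-n.
lm_examples <- function(texts, charset, context_len) {
  xs <- list(); ys <- list()
  for (s in seq_along(texts)) {
    code <- encode_chars(texts[s], charset)
    n <- length(code)
    padded <- c(rep(1L, context_len), code)
    ctx <- t(vapply(seq_len(n), function(t) {
      padded[t:(t + context_len - 1L)]
    }, integer(context_len)))
    xs[[s]] <- ctx
    ys[[s]] <- code
  }
  list(idx = do.call(rbind, xs), y = unlist(ys, use.names = FALSE))
}

lm_embed <- function(params, idx, embed_dim) {
  n <- nrow(idx); ctx <- ncol(idx)
  E <- matrix(0, n, ctx * embed_dim)
  for (j in seq_len(ctx)) {
    E[, ((j - 1L) * embed_dim + 1L):(j * embed_dim)] <-
      params$emb[idx[, j], , drop = FALSE]
  }
  E
}

lm_forward <- function(params, E) {
  H <- tanh(sweep(E %*% params$W1, 2, params$b1, "+"))
  logits <- sweep(H %*% params$W2, 2, params$b2, "+")
  # Row-stable softmax.
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  P <- ex / rowSums(ex)
  list(H = H, P = P)
}

#' Fine-tune the character-level model
#'
#' Minibatch Adam on the cross-entropy of next-character prediction over all
#' positions of every record's full sentence (`prompt + completion`). The
#' run is a pure function of the model, the records and `config$seed`; the
#' per-epoch mean negative log-likelihood is returned as the loss trace.
#'
#' @param model A [char_lm()].
#' @param records Data frame from [make_records()].
#' @param config A [finetune_config()]; `epochs`, `batch_size`, `seed` and
#'   `learning_rate` are used. `epochs = 0` returns the model unchanged with
#'   an empty trace.
#' @param ... Unused.
#' @return `list(model =, loss =)`.
#' @export
finetune.char_lm <- function(model, records, config = finetune_config(), ...) {
  stopifnot(inherits(config, "finetune_config"))
  if (config$epochs == 0L) {
    return(list(model = model, loss = numeric(0)))
  }
  texts <- if ("text" %in% names(records)) {
    records$text
  } else {
    paste0(records$prompt, records$completion)
  }
  data <- lm_examples(texts, model$charset, model$context_len)
  n <- length(data$y)
  d <- model$embed_dim
  p <- model$params
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  m_st <- lapply(p, function(x) x * 0)
  v_st <- lapply(p, function(x) x * 0)
  step <- 0L
  loss_trace <- numeric(config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        idx <- data$idx[rows, , drop = FALSE]
        y <- data$y[rows]
        nb <- length(rows)

        E <- lm_embed(p, idx, d)
        fw <- lm_forward(p, E)
        picked <- fw$P[cbind(seq_len(nb), y)]
        epoch_loss <- epoch_loss - sum(log(pmax(picked, 1e-12)))

        dlogits <- fw$P
        dlogits[cbind(seq_len(nb), y)] <- dlogits[cbind(seq_len(nb), y)] - 1
        dlogits <- dlogits / nb
        g <- list(
          W2 = crossprod(fw$H, dlogits),
          b2 = colSums(dlogits)
        )
        dH <- tcrossprod(dlogits, p$W2) * (1 - fw$H^2)
        g$W1 <- crossprod(E, dH)
        g$b1 <- colSums(dH)
        dE <- tcrossprod(dH, p$W1)
        # Scatter-add the embedding gradient over all context positions.
        ctx <- ncol(idx)
        flat_idx <- as.vector(idx)
        dE_rows <- do.call(rbind, lapply(seq_len(ctx), function(j) {
          dE[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
        }))
        acc <- rowsum(dE_rows, group = flat_idx)
        g$emb <- p$emb * 0
        g$emb[as.integer(rownames(acc)), ] <- acc

        step <- step + 1L
        for (nm in names(p)) {
          m_st[[nm]] <- beta1 * m_st[[nm]] + (1 - beta1) * g[[nm]]
          v_st[[nm]] <- beta2 * v_st[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- m_st[[nm]] / (1 - beta1^step)
          vhat <- v_st[[nm]] / (1 - beta2^step)
          p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_trace[epoch] <- epoch_loss / n
    }
  })
  model$params <- p
  list(model = model, loss = loss_trace)
}

#' @describeIn char_lm Greedy decoding: repeatedly predict the
#'   highest-probability next character until `max_chars` characters have
#'   been generated or the pad symbol is produced.
#' @param model,prompt,max_chars,... See [complete()].
#' @export
complete.char_lm <- function(model, prompt, max_chars = 16L, ...) {
  code <- encode_chars(prompt, model$charset)
  out <- integer(0)
  for (i in seq_len(max_chars)) {
    window <- c(rep(1L, model$context_len), code, out)
    window <- window[(length(window) - model$context_len + 1L):length(window)]
    E <- lm_embed(model$params, matrix(window, nrow = 1L), model$embed_dim)
    fw <- lm_forward(model$params, E)
    nxt <- which.max(fw$P[1L, ])
    if (nxt == 1L) break
    out <- c(out, nxt)
  }
  paste(model$charset[out], collapse = "")
}
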