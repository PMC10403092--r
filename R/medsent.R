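## Medication-history representation learning: medication event streams are
## rendered as ordered "sentences" of medication-name and action tokens,
## embedded with GloVe vectors trained on within-sentence co-occurrence, and
## summarized by a small 1-D convolutional classifier whose penultimate
## (max-pooled) layer provides the `medhist*` features.

VALID_ACTIONS <- c("given", "rate changed", "stopped")
LEAKY_SLOPE <- 0.05
PAD_TOKEN <- "<pad>"
EMPTY_TOKEN <- "<no_meds>"

normalize_token <- function(x) gsub(" +", "_", tolower(trimws(x)))

#' Build a medication-history sentence
#'
#' Events in the half-open window `(t - window, t]` are sorted by
#' `(time, sequence_no)` and emitted as alternating medication-name and
#' action tokens ("a given b given a rate_changed b stopped"). Names are
#' lowercased with spaces replaced by underscores; multi-word actions are
#' joined with underscores. An empty window yields the sentinel sentence
#' `"<no_meds>"`.
#'
#' @param medications medication events (`encounter_id`, `time`,
#'   `medication`, `action`, `sequence_no`).
#' @param encounter_id encounter to build the sentence for.
#' @param t anchor time (minutes since admission).
#' @param window_minutes lookback window; `Inf` for the full history up to
#'   `t`.
#' @return single character string of space-separated tokens.
#' @export
build_sentence <- function(medications, encounter_id, t, window_minutes = 360) {
  medications <- as.data.frame(medications)
  lo <- if (is.finite(window_minutes)) t - window_minutes else -Inf
  keep <- medications[["encounter_id"]] == encounter_id &
    medications[["time"]] > lo & medications[["time"]] <= t
  ev <- medications[keep, , drop = FALSE]
  bad <- setdiff(unique(ev$action), VALID_ACTIONS)
  if (length(bad))
    stop(sprintf("unknown medication action(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!nrow(ev)) return(EMPTY_TOKEN)
  ev <- ev[order(ev$time, ev$sequence_no), , drop = FALSE]
  paste(normalize_token(ev$medication), normalize_token(ev$action), collapse = " ")
}

#' Build the extractor training corpus
#'
#' One sentence per training encounter: for MV cases the full medication
#' history up to the MV preparation time, for no-MV cases the full length of
#' stay. Labels are the MV outcome.
#'
#' @param medications medication event table (training split only).
#' @param encounters encounter table (training split only).
#' @param prep_minutes preparation window before MV onset.
#' @return list with `sentences` (named by encounter id) and `labels` (0/1).
#' @export
build_training_corpus <- function(medications, encounters, prep_minutes = 30L) {
  enc <- as.data.frame(encounters)
  cutoff <- ifelse(enc$mv_flag, enc$mv_onset_time - prep_minutes, Inf)
  med_df <- as.data.frame(medications)
  by_enc <- split(med_df, factor(med_df$encounter_id, levels = enc$encounter_id))
  sentences <- vapply(seq_len(nrow(enc)), function(i)
    build_sentence(by_enc[[i]], enc$encounter_id[i], t = cutoff[i],
                   window_minutes = Inf), "")
  names(sentences) <- enc$encounter_id
  list(sentences = sentences, labels = as.integer(enc$mv_flag))
}

tokenize <- function(sentences) strsplit(sentences, " ", fixed = TRUE)

#' Within-sentence co-occurrence counts
#'
#' Symmetric token co-occurrence with a distance-weighted (1/d) scheme over a
#' fixed context window, accumulated across sentences; the raw ingredient of
#' the GloVe objective.
#'
#' @param sentences character vector of token sentences.
#' @param window context window size in tokens.
#' @param weighted down-weight pairs by 1/distance (GloVe convention); with
#'   `FALSE` each co-occurring pair counts 1.
#' @return data.table with columns `token_i`, `token_j`, `x` (symmetric).
#' @export
cooccurrence_counts <- function(sentences, window = 25L, weighted = TRUE) {
  toks <- tokenize(sentences)
  pairs <- vector("list", length(toks) * as.integer(window))
  k <- 0L
  for (s in toks) {
    n <- length(s)
    if (n < 2L) next
    for (d in seq_len(min(window, n - 1L))) {
      k <- k + 1L
      pairs[[k]] <- data.table::data.table(
        token_i = s[seq_len(n - d)], token_j = s[seq_len(n - d) + d],
        x = if (weighted) 1 / d else 1)
    }
  }
  if (k == 0L)
    return(data.table::data.table(token_i = character(), token_j = character(),
                                  x = numeric()))
  co <- data.table::rbindlist(pairs[seq_len(k)])
  ## symmetrize: count both directions
  co <- data.table::rbindlist(list(co, data.table::setnames(
    data.table::copy(co), c("token_i", "token_j"), c("token_j", "token_i"))),
    use.names = TRUE)
  co[, .(x = sum(x)), by = .(token_i, token_j)]
}

#' Fit GloVe token embeddings on a medication-sentence corpus
#'
#' Minimizes the weighted least-squares GloVe objective
#' `sum f(X_ij) (w_i . w~_j + b_i + b~_j - log X_ij)^2` on symmetric
#' within-sentence co-occurrence counts, by full-batch AdaGrad. The final
#' embedding of a token is `w + w~`. The padding token gets the zero vector;
#' tokens never observed in any co-occurrence also map to zero.
#'
#' @param sentences corpus sentences (one per encounter).
#' @param window context window size in tokens (default 25).
#' @param dim embedding dimension (default 10).
#' @param epochs AdaGrad iterations.
#' @param seed integer seed for initialization.
#' @param x_max,alpha GloVe weighting-function parameters
#'   `f(x) = min((x / x_max)^alpha, 1)`.
#' @param learning_rate AdaGrad learning rate.
#' @return object of class `med_embedding`: `vocab`, `vectors` (tokens x
#'   dim), `dim`, `window`. Out-of-vocabulary tokens map to the
#'   `"<no_meds>"` sentinel vector.
#' @export
fit_embeddings <- function(sentences, window = 25L, dim = 10L, epochs = 50L,
                           seed = 1L, x_max = 10, alpha = 0.75,
                           learning_rate = 0.05) {
  corpus_vocab <- sort(unique(unlist(tokenize(sentences), use.names = FALSE)))
  if (length(corpus_vocab) < 2L)
    stop("vocabulary too small: need at least 2 corpus tokens")
  vocab <- union(union(corpus_vocab, EMPTY_TOKEN), PAD_TOKEN)
  co <- cooccurrence_counts(sentences, window = window)
  V <- length(vocab)
  i <- match(co$token_i, vocab); j <- match(co$token_j, vocab)
  logx <- log(co$x)
  fw <- pmin((co$x / x_max)^alpha, 1)
  with_seed(seed, {
    W <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
    Wt <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
    b <- stats::runif(V, -0.5, 0.5) / dim
    bt <- stats::runif(V, -0.5, 0.5) / dim
    gW <- matrix(1e-8, V, dim); gWt <- matrix(1e-8, V, dim)
    gb <- rep(1e-8, V); gbt <- rep(1e-8, V)
    if (length(i)) {
      for (ep in seq_len(epochs)) {
        diff <- rowSums(W[i, , drop = FALSE] * Wt[j, , drop = FALSE]) +
          b[i] + bt[j] - logx
        g <- fw * diff
        dW <- rowsum(g * Wt[j, , drop = FALSE], i, reorder = FALSE)
        dWt <- rowsum(g * W[i, , drop = FALSE], j, reorder = FALSE)
        db <- rowsum(g, i, reorder = FALSE)
        dbt <- rowsum(g, j, reorder = FALSE)
        ri <- as.integer(rownames(dW)); rj <- as.integer(rownames(dWt))
        gW[ri, ] <- gW[ri, ] + dW^2
        W[ri, ] <- W[ri, ] - learning_rate * dW / sqrt(gW[ri, , drop = FALSE])
        gWt[rj, ] <- gWt[rj, ] + dWt^2
        Wt[rj, ] <- Wt[rj, ] - learning_rate * dWt / sqrt(gWt[rj, , drop = FALSE])
        gb[ri] <- gb[ri] + db[, 1]^2
        b[ri] <- b[ri] - learning_rate * db[, 1] / sqrt(gb[ri])
        gbt[rj] <- gbt[rj] + dbt[, 1]^2
        bt[rj] <- bt[rj] - learning_rate * dbt[, 1] / sqrt(gbt[rj])
      }
    }
    vec <- W + Wt
    rownames(vec) <- vocab
    unseen <- setdiff(vocab, unique(c(co$token_i, co$token_j)))
    vec[unseen, ] <- 0
    vec[PAD_TOKEN, ] <- 0
    structure(list(vocab = vocab, vectors = vec, dim = dim, window = window),
              class = "med_embedding")
  })
}

#' Convolutional extractor configuration
#'
#' Defaults: five filters per length for token-span lengths 4, 5 and 6
#' (feature dimension 5 x 3 = 15), filter width equal to the embedding
#' dimension, dropout 0.5, 40 epochs of momentum SGD at learning rate 3e-3,
#' batch 64, 10 cross-validation folds, head truncation of sentences to 512
#' most recent tokens.
#'
#' @param filter_lengths convolution spans in tokens.
#' @param filters_per_length filters per span length.
#' @param dropout_rate dropout on the pooled layer during training.
#' @param max_sentence_tokens pad/truncate length (most recent tokens kept).
#' @param epochs,batch_size,learning_rate optimizer settings.
#' @param folds cross-validation folds for training-performance confirmation
#'   (0 skips CV).
#' @param seed integer seed.
#' @return object of class `conv_extractor_config`.
#' @export
conv_extractor_config <- function(filter_lengths = c(4L, 5L, 6L),
                                  filters_per_length = 5L,
                                  dropout_rate = 0.5,
                                  max_sentence_tokens = 512L,
                                  epochs = 40L, batch_size = 64L,
                                  learning_rate = 3e-3, folds = 10L,
                                  seed = 1L) {
  stopifnot(all(filter_lengths >= 1), filters_per_length >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(filter_lengths = as.integer(filter_lengths),
                 filters_per_length = check_count(filters_per_length, "filters_per_length"),
                 dropout_rate = dropout_rate,
                 max_sentence_tokens = check_count(max_sentence_tokens, "max_sentence_tokens"),
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = check_pos(learning_rate, "learning_rate"),
                 folds = check_count(folds, "folds", min = 0L),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "conv_extractor_config")
}

sentence_ids <- function(sentences, vocab, max_tokens) {
  toks <- tokenize(sentences)
  sent_id <- match(EMPTY_TOKEN, vocab)
  lapply(toks, function(s) {
    if (length(s) > max_tokens) s <- s[(length(s) - max_tokens + 1L):length(s)]
    ids <- match(s, vocab)
    ids[is.na(ids)] <- sent_id
    ids
  })
}

## forward pass to the pooled layer for a batch of id sequences.
## Windows start at positions 1..len(s); positions beyond the sentence are
## zero vectors, so features depend only on the sentence, not batch padding.
conv_forward <- function(params, emb, ids_list, keep_cache = FALSE) {
  n <- length(ids_list)
  lens <- lengths(ids_list)
  d <- ncol(emb)
  Lmax <- max(params$filter_lengths)
  Tn <- max(lens, 1L) + Lmax - 1L
  pad_id <- params$pad_id
  ids_mat <- matrix(pad_id, n, Tn)
  for (ii in seq_len(n)) if (lens[ii]) ids_mat[ii, seq_len(lens[ii])] <- ids_list[[ii]]
  M <- emb[as.vector(ids_mat), , drop = FALSE]  # (n*Tn) x d, column-major in t
  pooled <- NULL; caches <- list()
  for (li in seq_along(params$filter_lengths)) {
    L <- params$filter_lengths[li]
    W <- params$W[[li]]; b <- params$b[[li]]
    Fk <- ncol(W)
    P <- max(lens, 1L)
    Z <- array(-Inf, dim = c(n, P, Fk))
    ## W rows are offset-major blocks of d dims: rows (l-1)*d + 1..d hold
    ## the filter weights for token offset l (the backward gather assumes
    ## the same layout)
    for (p in seq_len(P)) {
      Zp <- matrix(b, n, Fk, byrow = TRUE)
      for (l in seq_len(L)) {
        Zp <- Zp + M[(p + l - 2L) * n + seq_len(n), , drop = FALSE] %*%
          W[(l - 1L) * d + seq_len(d), , drop = FALSE]
      }
      Z[, p, ] <- Zp
    }
    valid <- outer(pmax(lens, 1L), seq_len(P), `>=`)
    Z[!as.vector(valid)] <- -Inf  # broadcast over filters
    zmax <- apply(Z, c(1, 3), max)
    pstar <- apply(Z, c(1, 3), which.max)
    ## leaky rectifier on the pooled maximum: filters whose maximum goes
    ## negative keep a small gradient path and can recover (a hard ReLU
    ## permanently kills them, since max-pooling gates all other gradients)
    h <- ifelse(zmax > 0, zmax, LEAKY_SLOPE * zmax)
    pooled <- cbind(pooled, h)
    if (keep_cache)
      caches[[li]] <- list(zmax = zmax, pstar = pstar, L = L)
  }
  list(pooled = pooled, caches = caches, M = M, n = n, Tn = Tn)
}

softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e1 <- exp(logits[, 1] - m); e2 <- exp(logits[, 2] - m)
  e2 / (e1 + e2)
}

## SGD with classical momentum. Scale-free optimizers (Adam-style
## per-coordinate normalization) are unsuitable here: early in training the
## convolutional gradients are noise-level (the zero-initialized head gates
## them), and normalizing turns that noise into full-size steps that
## random-walk the filters to death. Momentum SGD steps are proportional to
## the true gradient magnitude, so noise moves nothing and signal moves.
sgd_update <- function(state, grad, lr, momentum = 0.9) {
  state$m <- momentum * state$m + grad
  state$val <- state$val - lr * state$m
  state
}

train_cnn_core <- function(ids, labels, emb, cfg, epochs, seed) {
  d <- ncol(emb)
  Fk <- cfg$filters_per_length
  params <- list(filter_lengths = cfg$filter_lengths,
                 pad_id = attr(emb, "pad_id"))
  with_seed(seed, {
    params$W <- lapply(cfg$filter_lengths, function(L)
      matrix(stats::rnorm(L * d * Fk, 0, sqrt(2 / (L * d))), L * d, Fk))
    params$b <- lapply(cfg$filter_lengths, function(L) rep(0, Fk))
    ## frozen standardization of the pooled layer, fit once at
    ## initialization over the whole corpus: max-pooled conv features have
    ## tiny and very unequal scales, and without this the logistic head
    ## would need enormous weights (far beyond what gradient steps reach)
    ## to exploit their class separation
    h0 <- matrix(0, length(ids), Fk * length(cfg$filter_lengths))
    for (s0 in seq(1L, length(ids), by = 256L)) {
      b0 <- s0:min(s0 + 255L, length(ids))
      h0[b0, ] <- conv_forward(params, emb, ids[b0])$pooled
    }
    params$h_mu <- colMeans(h0)
    params$h_sd <- pmax(apply(h0, 2, stats::sd), 1e-4)
    Ftot <- Fk * length(cfg$filter_lengths)
    ## zero-initialized output layer: the first updates fit a linear probe
    ## on the (random but already expressive) pooled features, and the
    ## convolution then fine-tunes without the early activation collapse a
    ## randomly-initialized head induces
    U <- matrix(0, Ftot, 2)
    cvec <- c(0, 0)
    ## class-weighted loss keeps the minority (MV) class from being ignored
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    wcls <- c(`0` = length(labels) / (2 * n0), `1` = length(labels) / (2 * n1))
    st <- list()
    mk <- function(x) list(val = x, m = x * 0)
    for (li in seq_along(params$W)) {
      st[[paste0("W", li)]] <- mk(params$W[[li]])
      st[[paste0("b", li)]] <- mk(params$b[[li]])
    }
    st$U <- mk(U); st$c <- mk(cvec)
    step <- 0L
    n <- length(ids)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, n)]
        fw <- conv_forward(params, emb, ids[bi], keep_cache = TRUE)
        h <- sweep(sweep(fw$pooled, 2, params$h_mu), 2, params$h_sd, "/")
        if (cfg$dropout_rate > 0) {
          mask <- matrix(stats::runif(length(h)) >= cfg$dropout_rate,
                         nrow(h), ncol(h)) / (1 - cfg$dropout_rate)
          hd <- h * mask
        } else { mask <- NULL; hd <- h }
        logits <- hd %*% st$U$val + matrix(st$c$val, nrow(hd), 2, byrow = TRUE)
        p1 <- softmax2(logits)
        y <- labels[bi]
        wv <- wcls[as.character(y)]
        dlog <- cbind((1 - p1) - (y == 0L), p1 - (y == 1L)) * wv / length(bi)
        dU <- t(hd) %*% dlog
        dc <- colSums(dlog)
        dhd <- dlog %*% t(st$U$val)
        dh <- if (is.null(mask)) dhd else dhd * mask
        dh <- sweep(dh, 2, params$h_sd, "/")  # through the frozen scaling
        step <- step + 1L
        st$U <- sgd_update(st$U, dU, cfg$learning_rate)
        st$c <- sgd_update(st$c, dc, cfg$learning_rate)
        ## route pooled gradients back to conv weights at the argmax windows
        lens <- lengths(ids[bi]); nb <- length(bi)
        for (li in seq_along(params$W)) {
          cache <- fw$caches[[li]]
          cols <- (li - 1L) * Fk + seq_len(Fk)
          dzmax <- dh[, cols, drop = FALSE] *
            ifelse(cache$zmax > 0, 1, LEAKY_SLOPE)
          dW <- st[[paste0("W", li)]]$val * 0
          db <- rep(0, Fk)
          L <- cache$L
          for (f in seq_len(Fk)) {
            nz <- which(dzmax[, f] != 0)
            if (!length(nz)) next
            p <- cache$pstar[nz, f]
            ## gather the selected windows: row index in M is (t-1)*nb + i
            Xsel <- matrix(0, length(nz), L * ncol(emb))
            for (l in seq_len(L)) {
              ridx <- (p + l - 2L) * nb + nz
              Xsel[, (l - 1L) * ncol(emb) + seq_len(ncol(emb))] <-
                fw$M[ridx, , drop = FALSE]
            }
            dW[, f] <- t(Xsel) %*% dzmax[nz, f]
            db[f] <- sum(dzmax[nz, f])
          }
          ## clip the conv gradient: the standardization backward magnifies
          ## low-variance feature gradients by 1/sd
          gn <- sqrt(sum(dW^2) + sum(db^2))
          if (gn > 0.5) { dW <- dW * 0.5 / gn; db <- db * 0.5 / gn }
          st[[paste0("W", li)]] <- sgd_update(st[[paste0("W", li)]], dW,
                                              cfg$learning_rate)
          st[[paste0("b", li)]] <- sgd_update(st[[paste0("b", li)]], db,
                                              cfg$learning_rate)
          params$W[[li]] <- st[[paste0("W", li)]]$val
          params$b[[li]] <- st[[paste0("b", li)]]$val
        }
      }
    }
    list(params = params, U = st$U$val, c = st$c$val)
  })
}

cnn_predict_prob <- function(model, emb, ids, batch = 256L) {
  n <- length(ids)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    bi <- start:min(start + batch - 1L, n)
    fw <- conv_forward(model$params, emb, ids[bi])
    h <- sweep(sweep(fw$pooled, 2, model$params$h_mu), 2, model$params$h_sd, "/")
    logits <- h %*% model$U + matrix(model$c, length(bi), 2, byrow = TRUE)
    out[bi] <- softmax2(logits)
  }
  out
}

#' Train the medication-history convolutional extractor
#'
#' Trains the sentence classifier (frozen GloVe embedding, one convolutional
#' layer with ReLU, max-pooling over token positions, dropout, softmax
#' binary output) with optional stratified k-fold cross-validation for
#' performance confirmation, then refits on all sentences. The returned
#' extractor is frozen; its forward pass stops at the max-pooled layer just
#' before the binary output, which defines the `medhist*` features.
#'
#' @param sentences training sentences (one per encounter).
#' @param labels binary outcome per sentence.
#' @param cfg a [conv_extractor_config()].
#' @param embeddings a [fit_embeddings()] model.
#' @return object of class `med_extractor` with elements `params`, `U`, `c`,
#'   `embedding`, `config`, `cv_auroc` (NA when `folds = 0`),
#'   `n_features`.
#' @export
train_extractor <- function(sentences, labels, cfg = conv_extractor_config(),
                            embeddings) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train the extractor")
  stopifnot(inherits(embeddings, "med_embedding"))
  emb <- embeddings$vectors
  attr(emb, "pad_id") <- match(PAD_TOKEN, embeddings$vocab)
  ids <- sentence_ids(sentences, embeddings$vocab, cfg$max_sentence_tokens)

  cv_auroc <- NA_real_
  if (cfg$folds > 1L) {
    folds <- with_seed(cfg$seed, stratified_folds(labels, cfg$folds))
    oof <- rep(NA_real_, length(ids))
    for (k in seq_len(cfg$folds)) {
      tr <- folds != k
      if (length(unique(labels[tr])) < 2L || length(unique(labels[!tr])) < 2L)
        stop("both classes must be present in every fold")
      m <- train_cnn_core(ids[tr], labels[tr], emb, cfg, cfg$epochs,
                          seed = derive_seed(cfg$seed, "cnn") + k)
      oof[!tr] <- cnn_predict_prob(m, emb, ids[!tr])
    }
    cv_auroc <- auroc(oof, labels)
  }
  fit <- train_cnn_core(ids, labels, emb, cfg, cfg$epochs,
                        seed = derive_seed(cfg$seed, "cnn"))
  structure(list(params = fit$params, U = fit$U, c = fit$c,
                 embedding = embeddings, config = cfg, cv_auroc = cv_auroc,
                 n_features = cfg$filters_per_length * length(cfg$filter_lengths)),
            class = "med_extractor")
}

## stratified fold assignment (also used by the risk model)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Extract medication-history features from a frozen extractor
#'
#' Deterministic forward pass (dropout disabled) stopping at the max-pooled
#' layer; returns one `medhist1..F` row per sentence.
#'
#' @param extractor a frozen [train_extractor()] model.
#' @param sentences character vector of medication sentences.
#' @return numeric matrix with `extractor$n_features` named columns.
#' @export
extract_medhist <- function(extractor, sentences) {
  stopifnot(inherits(extractor, "med_extractor"))
  emb <- extractor$embedding$vectors
  attr(emb, "pad_id") <- match(PAD_TOKEN, extractor$embedding$vocab)
  ids <- sentence_ids(sentences, extractor$embedding$vocab,
                      extractor$config$max_sentence_tokens)
  out <- matrix(NA_real_, length(ids), extractor$n_features,
                dimnames = list(NULL, paste0("medhist", seq_len(extractor$n_features))))
  for (start in seq(1L, length(ids), by = 256L)) {
    bi <- start:min(start + 255L, length(ids))
    fw <- conv_forward(extractor$params, emb, ids[bi])
    out[bi, ] <- sweep(sweep(fw$pooled, 2, extractor$params$h_mu), 2,
                       extractor$params$h_sd, "/")
  }
  out
}

#' Predict MV probability from medication sentences
#'
#' Full forward pass of the frozen sentence classifier (used for
#' cross-validation checks; the pipeline consumes the pooled features).
#'
#' @inheritParams extract_medhist
#' @return numeric vector of class-1 probabilities.
#' @export
predict_sentence_prob <- function(extractor, sentences) {
  stopifnot(inherits(extractor, "med_extractor"))
  emb <- extractor$embedding$vectors
  attr(emb, "pad_id") <- match(PAD_TOKEN, extractor$embedding$vocab)
  ids <- sentence_ids(sentences, extractor$embedding$vocab,
                      extractor$config$max_sentence_tokens)
  cnn_predict_prob(list(params = extractor$params, U = extractor$U,
                        c = extractor$c), emb, ids)
}

## medhist features evaluated at sentence change points, then carried
## forward onto the 5-minute grid (the 6-h window sentence only changes when
## an event enters or leaves the window)
medhist_on_grid <- function(extractor, medications, grid, window_minutes = 360L,
                            grid_step = 5L) {
  F <- extractor$n_features
  cols <- paste0("medhist", seq_len(F))
  encs <- unique(grid$encounter_id)
  meds <- data.table::as.data.table(medications)[encounter_id %in% encs]
  ceil_grid <- function(t) as.integer(ceiling(t / grid_step) * grid_step)
  if (nrow(meds)) {
    cp <- data.table::rbindlist(list(
      meds[, .(encounter_id, time = ceil_grid(time))],
      meds[, .(encounter_id, time = ceil_grid(time + window_minutes))],
      data.table::data.table(encounter_id = encs, time = 0L)))
    gmax <- grid[, .(tmax = max(time)), by = encounter_id]
    cp <- merge(unique(cp), gmax, by = "encounter_id")[time <= tmax][, tmax := NULL]
  } else {
    cp <- data.table::data.table(encounter_id = encs, time = 0L)
  }
  ## gather window tokens via non-equi join
  cp[, win_id := .I]
  cp[, `:=`(lo = time - window_minutes, hi = time)]
  toks <- meds[cp, on = .(encounter_id, time > lo, time <= hi),
               .(win_id = i.win_id, ev_time = x.time, seq = x.sequence_no,
                 medication = x.medication, action = x.action),
               nomatch = NULL, allow.cartesian = TRUE]
  sent <- rep(EMPTY_TOKEN, nrow(cp))
  if (nrow(toks)) {
    data.table::setorder(toks, win_id, ev_time, seq)
    built <- toks[, .(s = paste(normalize_token(medication),
                                normalize_token(action), collapse = " ")),
                  by = win_id]
    sent[built$win_id] <- built$s
  }
  usent <- unique(sent)
  feats_u <- extract_medhist(extractor, usent)
  feats <- feats_u[match(sent, usent), , drop = FALSE]
  cpf <- cbind(cp[, .(encounter_id, time)], data.table::as.data.table(feats))
  data.table::setkey(cpf, encounter_id, time)
  out <- cpf[grid[, .(encounter_id, time)], on = c("encounter_id", "time"),
             roll = TRUE]
  m <- as.matrix(out[, ..cols])
  ## grid rows before the first change point (none exist other than t=0) are 0
  m[is.na(m)] <- 0
  m
}
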