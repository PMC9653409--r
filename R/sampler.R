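# Generation: interpolation sampling of conditioning vectors,
# autoregressive decoding from <SOS>, and library post-processing
# (validity, deduplication against the training corpora, structural
# alerts) with exact per-attempt accounting.

#' Linear interpolation of state vectors
#'
#' `(1 - alpha) * h_i + alpha * h_j`. Endpoints (`alpha` 0 or 1) are
#' permitted for testing; library sampling draws `alpha` strictly
#' inside (0, 1).
#'
#' @param h_i,h_j numeric vectors of equal length.
#' @param alpha interpolation factor in `[0, 1]`.
#' @return numeric vector.
#' @export
linear_interp <- function(h_i, h_j, alpha) {
  if (length(h_i) != length(h_j))
    stop2("state vectors differ in length")
  stopifnot(alpha >= 0, alpha <= 1)
  (1 - alpha) * h_i + alpha * h_j
}

#' Spherical interpolation (slerp) of state vectors
#'
#' `sin((1 - beta) * theta) / sin(theta) * h_i +
#'  sin(beta * theta) / sin(theta) * h_j`, with `theta` the central
#' angle between the two vectors. For nearly collinear vectors
#' (`theta < 1e-6` rad) the sine ratio degenerates and the function
#' falls back to linear interpolation.
#'
#' @param h_i,h_j numeric vectors of equal length, neither all-zero.
#' @param beta interpolation factor in `[0, 1]`.
#' @return numeric vector.
#' @export
slerp_interp <- function(h_i, h_j, beta) {
  if (length(h_i) != length(h_j))
    stop2("state vectors differ in length")
  stopifnot(beta >= 0, beta <= 1)
  ni <- sqrt(sum(h_i^2)); nj <- sqrt(sum(h_j^2))
  if (ni == 0 || nj == 0)
    stop2("slerp is undefined for a zero vector")
  ct <- sum(h_i * h_j) / (ni * nj)
  theta <- acos(pmin(pmax(ct, -1), 1))
  if (theta < 1e-6) return(linear_interp(h_i, h_j, beta))
  (sin((1 - beta) * theta) * h_i + sin(beta * theta) * h_j) / sin(theta)
}

#' Single-point sampling around a state vector
#'
#' `h_i + xi_s` with `xi_s ~ N(mu_s, sigma_s^2)` i.i.d. per coordinate.
#'
#' @param h_i numeric vector.
#' @param noise a [noise_spec()].
#' @return numeric vector of the same length.
#' @export
single_point_sample <- function(h_i, noise) regularize_state(h_i, noise)

#' Sampling configuration for library generation
#'
#' @param mode conditioning-vector construction: `"linear"` (default;
#'   the best-performing scheme), `"slerp"`, or `"single_point"`.
#' @param alpha,beta fixed interpolation factor in (0, 1); `NULL` draws
#'   a fresh uniform factor per sample.
#' @param sigma_s,mu_s Gaussian parameters for single-point mode.
#' @param n_samples number of decoding attempts.
#' @param max_len decoding length cap.
#' @param temperature softmax temperature for multinomial decoding
#'   (values `<= 1e-6` decode greedily).
#' @param seed integer seed controlling pair choice, factors and token
#'   sampling.
#' @return object of class `sampling_config`.
#' @export
sampling_config <- function(mode = c("linear", "slerp", "single_point"),
                            alpha = NULL, beta = NULL, sigma_s = 0.1,
                            mu_s = 0, n_samples = 1000L, max_len = 120L,
                            temperature = 1.0, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.null(alpha) && (alpha <= 0 || alpha >= 1))
    stop2("alpha must lie strictly inside (0, 1)")
  if (!is.null(beta) && (beta <= 0 || beta >= 1))
    stop2("beta must lie strictly inside (0, 1)")
  stopifnot(sigma_s >= 0, n_samples >= 1, max_len >= 1, temperature >= 0)
  structure(list(mode = mode, alpha = alpha, beta = beta,
                 sigma_s = sigma_s, mu_s = mu_s,
                 n_samples = as.integer(n_samples),
                 max_len = as.integer(max_len),
                 temperature = temperature, seed = as.integer(seed)),
            class = "sampling_config")
}

#' Decode one molecule from a conditioning vector
#'
#' Starts the decoder from `h0` with the `<SOS>` token and draws tokens
#' from the temperature-scaled softmax (multinomial; greedy argmax when
#' `temperature <= 1e-6`) until `<EOS>` or `max_len` tokens.
#'
#' @param ckpt a `crnn_checkpoint`.
#' @param h0 numeric conditioning vector.
#' @param max_len maximum number of generated tokens.
#' @param temperature softmax temperature.
#' @param seed optional seed (caller's RNG stream is preserved).
#' @return the raw generated string, or `NA_character_` when `max_len`
#'   is reached without `<EOS>`.
#' @export
generate_one <- function(ckpt, h0, max_len = 120L, temperature = 1.0,
                         seed = NULL) {
  stopifnot(inherits(ckpt, "crnn_checkpoint"))
  with_seed(seed, generate_one_impl(ckpt, h0, max_len, temperature))
}

generate_one_impl <- function(ckpt, h0, max_len, temperature) {
  p <- ckpt$params
  vocab <- ckpt$vocab
  Hd <- nrow(p$de_Wh)
  if (length(h0) != Hd)
    stop2("h0 has length ", length(h0), ", expected ", Hd)
  h <- matrix(h0, 1); c <- matrix(0, 1, Hd)
  cur <- vocab_id(vocab, "<SOS>")
  eos <- vocab_id(vocab, "<EOS>")
  out <- integer(0)
  for (t in seq_len(max_len)) {
    x <- matrix(0, 1, vocab$J); x[1, cur] <- 1
    st <- lstm_step(x, h, c, p$de_Wx, p$de_Wh, p$de_b, 1)
    h <- st$h; c <- st$c
    logit <- as.numeric(h %*% p$out_W + p$out_b)
    nxt <- if (temperature <= 1e-6) which.max(logit) else {
      pr <- exp((logit - max(logit)) / temperature)
      sample.int(vocab$J, 1L, prob = pr / sum(pr))
    }
    if (nxt == eos) return(decode_tokens(c(out, eos), vocab))
    out <- c(out, nxt)
    cur <- nxt
  }
  NA_character_
}

# Draw a conditioning vector from the encoded target states per the
# sampling mode. `H` is the [N x dim] matrix of target state vectors.
draw_state <- function(H, s_cfg) {
  N <- nrow(H)
  if (s_cfg$mode == "single_point") {
    i <- sample.int(N, 1L)
    list(h0 = H[i, ] + stats::rnorm(ncol(H), s_cfg$mu_s, s_cfg$sigma_s),
         i = i, j = NA_integer_, factor = NA_real_)
  } else {
    ij <- sample.int(N, 2L)
    fac <- if (s_cfg$mode == "linear") s_cfg$alpha %||% stats::runif(1)
           else s_cfg$beta %||% stats::runif(1)
    h0 <- if (s_cfg$mode == "linear")
      linear_interp(H[ij[1], ], H[ij[2], ], fac)
    else slerp_interp(H[ij[1], ], H[ij[2], ], fac)
    list(h0 = h0, i = ij[1], j = ij[2], factor = fac)
  }
}

#' Generate a post-processed virtual library
#'
#' Encodes the target corpus, draws conditioning vectors per the
#' sampling configuration (distinct random pairs with per-sample
#' interpolation factors by default), decodes each attempt, and
#' standardizes the results. Invalid strings, duplicates within the
#' run, duplicates of any training-corpus molecule, and molecules
#' matching a structural alert are removed, with each attempt counted
#' in exactly one bucket so that
#' `attempts == kept + invalid + duplicate_internal +
#'  duplicate_vs_training + alert_hits`.
#'
#' @param ckpt a `crnn_checkpoint`.
#' @param target_corpus standardized molecules whose states seed the
#'   sampling.
#' @param s_cfg a [sampling_config()].
#' @param training_corpora list of corpora (standardized data frames or
#'   SMILES vectors) the library must not duplicate; typically
#'   `list(source, target)`.
#' @param alerts alert table (see [default_alerts()]).
#' @return object of class `generated_set`: list with `molecules`
#'   (data frame `id`, `smiles`, `pair_i`, `pair_j`, `factor`),
#'   `counters`, and the config.
#' @export
build_library <- function(ckpt, target_corpus, s_cfg = sampling_config(),
                          training_corpora = list(target_corpus),
                          alerts = default_alerts()) {
  stopifnot(inherits(ckpt, "crnn_checkpoint"),
            inherits(s_cfg, "sampling_config"))
  tgt <- corpus_smiles(target_corpus)
  if (s_cfg$mode != "single_point" && length(tgt) < 2L)
    stop2("interpolation sampling needs at least two target molecules")
  H <- do.call(rbind, lapply(tgt, encode_state, ckpt = ckpt))
  known <- unique(unlist(lapply(training_corpora, corpus_smiles)))
  draws <- with_seed(s_cfg$seed, {
    lapply(seq_len(s_cfg$n_samples), function(k) {
      d <- draw_state(H, s_cfg)
      d$raw <- generate_one_impl(ckpt, d$h0, s_cfg$max_len,
                                 s_cfg$temperature)
      d
    })
  })
  raw <- vapply(draws, `[[`, character(1), "raw")
  counters <- c(attempts = s_cfg$n_samples, kept = 0L, invalid = 0L,
                duplicate_internal = 0L, duplicate_vs_training = 0L,
                alert_hits = 0L)
  std <- rep(NA_character_, length(raw))
  parseable <- !is.na(raw) & nzchar(raw)
  if (any(parseable)) {
    sr <- standardize_smiles(raw[parseable])
    std[parseable] <- ifelse(sr$status == "ok", sr$smiles, NA_character_)
  }
  uniq <- unique(std[!is.na(std)])
  alert_map <- if (length(uniq))
    stats::setNames(alert_counts(uniq, alerts), uniq) else integer(0)
  n_alerts_of <- function(s) alert_map[[s]]
  keep_rows <- list(); seen <- character(0)
  for (k in seq_along(raw)) {
    if (is.na(std[k])) { counters["invalid"] <- counters["invalid"] + 1L; next }
    if (std[k] %in% seen) {
      counters["duplicate_internal"] <- counters["duplicate_internal"] + 1L
      next
    }
    seen <- c(seen, std[k])
    if (std[k] %in% known) {
      counters["duplicate_vs_training"] <-
        counters["duplicate_vs_training"] + 1L
      next
    }
    if (n_alerts_of(std[k]) > 0) {
      counters["alert_hits"] <- counters["alert_hits"] + 1L
      next
    }
    counters["kept"] <- counters["kept"] + 1L
    keep_rows[[length(keep_rows) + 1L]] <-
      data.frame(smiles = std[k], pair_i = draws[[k]]$i,
                 pair_j = draws[[k]]$j, factor = draws[[k]]$factor,
                 stringsAsFactors = FALSE)
  }
  mols <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    data.frame(smiles = character(0), pair_i = integer(0),
               pair_j = integer(0), factor = numeric(0))
  if (!nrow(mols)) warning("no molecules survived post-processing")
  mols <- cbind(data.frame(id = if (nrow(mols))
    paste0("gen_", seq_len(nrow(mols))) else character(0),
    stringsAsFactors = FALSE), mols)
  structure(list(molecules = mols, counters = as.list(counters),
                 config = s_cfg),
            class = "generated_set")
}

#' @export
print.generated_set <- function(x, ...) {
  ct <- x$counters
  cat("Generated library:", ct$kept, "molecules from", ct$attempts,
      "attempts\n")
  cat("  removed: invalid", ct$invalid, "| internal duplicates",
      ct$duplicate_internal, "| training duplicates",
      ct$duplicate_vs_training, "| structural alerts",
      ct$alert_hits, "\n")
  invisible(x)
}
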