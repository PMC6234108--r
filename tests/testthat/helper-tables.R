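# Small in-code fixtures shared across the suite.

# descriptor_table straight from a matrix (+ optional target)
dt_from_matrix <- function(X, y = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("c%03d", seq_len(nrow(X)))
  df <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(X))
  if (!is.null(y)) df$logBCF <- y
  descriptor_table(df)
}

# generic p-descriptor table with planted linear slopes and gaussian noise
make_linear_table <- function(n, p, slopes, intercept = 0, noise_sd = 0,
                              seed = 1) {
  nms <- paste0("d", seq_len(p))
  eff <- lapply(seq_along(slopes), function(j) {
    list(type = "linear", slope = slopes[j])
  })
  names(eff) <- nms[seq_along(slopes)]
  spec <- synthetic_spec(n, descriptor_names = nms, collinear_pairs = list(),
                        effects = eff, intercept = intercept,
                        noise_sd = noise_sd, seed = seed)
  ds <- generate_dataset(spec)
  list(table = ds$table, truth = ds$truth, spec = spec)
}

even_split <- function(table, frac_train = 0.7, seed = 1) {
  n <- n_compounds(table)
  v <- floor(n * (1 - frac_train) / 2)
  split_dataset(table, c(n - 2 * v, v, v), seed = seed)
}
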