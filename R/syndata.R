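#' Configuration for the synthetic single-cell generator
#'
#' Builds and validates the parameter set for [simulate_states()]. The
#' defaults describe a desk-scale analogue of a patient-derived melanoma
#' scRNA-seq cohort: four transcriptional states with dedicated marker
#' programs, several patients contributing batch structure, log-normal
#' expression with additive log-space noise and expression-dependent
#' dropout.
#'
#' @param n_states Number of cell states.
#' @param n_genes Total number of genes.
#' @param markers_per_state Number of marker genes private to each state.
#' @param n_cells_per_state Cells simulated per state.
#' @param n_bulk_samples Default number of bulk mixtures for [simulate_bulk()].
#' @param marker_effect Fold-change multiplier on marker means: a marker's
#'   mean TPM in its own state is `(1 + marker_effect)` times its baseline,
#'   so `marker_effect = 0` leaves all states identical.
#' @param noise_sd SD of the additive Gaussian noise in log2 space.
#' @param dropout_rate Dropout probability at zero expression; the per-entry
#'   dropout probability decays as `dropout_rate * exp(-mu/2)` where `mu` is
#'   the entry's noiseless state mean in log2(TPM+1).
#' @param n_patients Number of patient/batch groups.
#' @param batch_sd SD of the per-patient per-gene log-space shift.
#' @param seed Integer RNG seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_states = 4, n_genes = 1000, markers_per_state = 50,
                         n_cells_per_state = 100, n_bulk_samples = 50,
                         marker_effect = 4, noise_sd = 1, dropout_rate = 0.3,
                         n_patients = 5, batch_sd = 0.3, seed = 1) {
  cfg <- list(n_states = n_states, n_genes = n_genes,
              markers_per_state = markers_per_state,
              n_cells_per_state = n_cells_per_state,
              n_bulk_samples = n_bulk_samples, marker_effect = marker_effect,
              noise_sd = noise_sd, dropout_rate = dropout_rate,
              n_patients = n_patients, batch_sd = batch_sd, seed = seed)
  counts <- c("n_states", "n_genes", "markers_per_state", "n_cells_per_state",
              "n_bulk_samples", "n_patients")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop("synth_config: '", f, "' must be an integer >= 1")
  }
  for (f in c("marker_effect", "noise_sd", "batch_sd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop("synth_config: '", f, "' must be a non-negative number")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("synth_config: 'dropout_rate' must be in [0, 1)")
  if (cfg$markers_per_state * cfg$n_states > cfg$n_genes)
    stop("synth_config: 'markers_per_state' x 'n_states' exceeds 'n_genes'")
  if (length(cfg$seed) != 1 || cfg$seed != round(cfg$seed))
    stop("synth_config: 'seed' must be a single integer")
  class(cfg) <- "synth_config"
  cfg
}

#' Simulate multi-state single-cell expression with ground truth
#'
#' Generates a log2(TPM+1) single-cell matrix with `n_states` states. Each
#' state owns `markers_per_state` private marker genes whose mean TPM is
#' elevated `(1 + marker_effect)`-fold in that state. Cells are assigned to
#' patients at random; each patient contributes a per-gene log-space shift
#' (batch effect). Gaussian noise is added in log space, values are clamped
#' at zero, then dropout zeroes entries with probability decaying in the
#' entry's noiseless state mean. Marker genes are drawn with low baseline
#' expression (off at baseline, induced in their state), the typical
#' behaviour of state-restricted programs such as pigmentation genes.
#'
#' @param config A [synth_config()].
#' @return A list with `cells` (an [expression_matrix()] in logTPM space)
#'   and `truth`, a `ground_truth` list with `state_of_cell`, `state_means`
#'   (gene x state, log2(TPM+1), noiseless), `marker_genes` (per-state list),
#'   `patient_of_cell`, and the config.
#' @export
simulate_states <- function(config) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, as.list(config))
  set.seed(config$seed)
  G <- config$n_genes; S <- config$n_states
  genes <- sprintf("g%04d", seq_len(G))
  states <- paste0("state", seq_len(S))
  marker_idx <- split(seq_len(config$markers_per_state * S),
                      rep(seq_len(S), each = config$markers_per_state))
  is_marker <- matrix(FALSE, G, S)
  for (s in seq_len(S)) is_marker[marker_idx[[s]], s] <- TRUE

  base <- stats::runif(G, 0.5, 6)
  base[rowSums(is_marker) > 0] <- stats::runif(sum(is_marker), 0.5, 1.5)
  state_means <- matrix(base, G, S, dimnames = list(genes, states))
  state_means <- state_means + is_marker * log2(1 + config$marker_effect)

  n_cells <- config$n_cells_per_state * S
  state_of_cell <- rep(states, each = config$n_cells_per_state)
  cells <- sprintf("c%04d", seq_len(n_cells))
  names(state_of_cell) <- cells
  patient_of_cell <- sample(paste0("patient", seq_len(config$n_patients)),
                            n_cells, replace = TRUE)
  names(patient_of_cell) <- cells
  batch <- matrix(stats::rnorm(G * config$n_patients, 0, config$batch_sd),
                  G, config$n_patients,
                  dimnames = list(genes, paste0("patient",
                                                seq_len(config$n_patients))))

  mu <- state_means[, match(state_of_cell, states), drop = FALSE]
  x <- mu + batch[, patient_of_cell, drop = FALSE] +
    matrix(stats::rnorm(G * n_cells, 0, config$noise_sd), G, n_cells)
  x <- pmax(x, 0)
  if (config$dropout_rate > 0) {
    p_drop <- config$dropout_rate * exp(-mu / 2)
    x[matrix(stats::runif(G * n_cells), G, n_cells) < p_drop] <- 0
  }
  dimnames(x) <- list(genes, cells)

  truth <- structure(list(
    state_of_cell = state_of_cell,
    state_means = state_means,
    marker_genes = lapply(marker_idx, function(i) genes[i]),
    patient_of_cell = patient_of_cell,
    proportions = NULL,
    drug_class_of = NULL,
    config = config), class = "ground_truth")
  names(truth$marker_genes) <- states
  list(cells = expression_matrix(x, "logTPM"), truth = truth)
}

# Dirichlet(1,...,1) rows via normalized gamma draws.
rdirichlet1 <- function(n, k) {
  g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
  g / rowSums(g)
}

#' Simulate bulk samples as known mixtures of state profiles
#'
#' Each bulk profile is a proportion-weighted average of the noiseless state
#' mean profiles in linear TPM space (physical mixtures average linear
#' abundances), then log2(TPM+1)-transformed, with Gaussian noise added in
#' log space. Mixing proportions default to Dirichlet(1,...,1) draws.
#'
#' @param truth `ground_truth` from [simulate_states()].
#' @param n_samples Number of bulk samples.
#' @param noise_sd SD of log-space Gaussian noise.
#' @param seed Integer RNG seed.
#' @param proportions Optional samples x states matrix of mixing weights
#'   (rows must sum to 1); overrides `n_samples` rows if given.
#' @return List with `bulk` (an [expression_matrix()], logTPM) and
#'   `proportions` (the mixing weights actually used).
#' @export
simulate_bulk <- function(truth, n_samples = truth$config$n_bulk_samples,
                          noise_sd = 0.1, seed = 1, proportions = NULL) {
  if (is.null(truth$state_means)) stop("truth$state_means is required")
  S <- ncol(truth$state_means)
  if (!is.null(proportions)) {
    proportions <- as.matrix(proportions)
    if (ncol(proportions) != S)
      stop("proportions must have one column per state")
    if (any(abs(rowSums(proportions) - 1) > 1e-9))
      stop("proportion rows must sum to 1")
    n_samples <- nrow(proportions)
  } else {
    if (!is.numeric(n_samples) || n_samples < 1)
      stop("n_samples must be >= 1")
    set.seed(seed)
    proportions <- rdirichlet1(n_samples, S)
  }
  set.seed(seed + 1L)
  tpm_means <- 2^truth$state_means - 1
  mix <- tpm_means %*% t(proportions)                 # genes x samples, TPM
  x <- log2(mix + 1)
  if (noise_sd > 0)
    x <- pmax(x + matrix(stats::rnorm(length(x), 0, noise_sd),
                         nrow(x), ncol(x)), 0)
  samples <- sprintf("b%04d", seq_len(n_samples))
  dimnames(x) <- list(rownames(truth$state_means), samples)
  dimnames(proportions) <- list(samples, colnames(truth$state_means))
  list(bulk = expression_matrix(x, "logTPM"), proportions = proportions)
}

#' Simulate mechanism-class-structured drug signatures
#'
#' Emulates a catalogue of drug perturbation differential-expression
#' signatures organised into mechanism-of-action classes. Each class has a
#' prototype signature (`genes_per_signature` genes drawn from the universe,
#' half up- and half down-regulated); each drug perturbs the prototype by
#' resampling every gene's symbol (up/down/absent) with probability
#' `flip_rate`, drawing uniformly from the other two symbols.
#'
#' @param n_classes Number of mechanism classes.
#' @param drugs_per_class Drugs per class.
#' @param genes_per_signature Genes in each prototype signature.
#' @param universe Character vector of candidate genes.
#' @param flip_rate Per-gene perturbation probability.
#' @param seed Integer RNG seed.
#' @return A [drug_signature_set()] with a `class_of` attribute-style field
#'   recording each drug's generating class.
#' @export
simulate_drug_signatures <- function(n_classes = 6, drugs_per_class = 10,
                                     genes_per_signature = 80,
                                     universe, flip_rate = 0.02, seed = 1) {
  if (length(universe) == 0) stop("gene universe must be non-empty")
  if (genes_per_signature > length(universe))
    stop("genes_per_signature exceeds universe size")
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  set.seed(seed)
  universe <- as.character(universe)
  n_up <- ceiling(genes_per_signature / 2)
  protos <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    sig <- integer(length(universe))
    picked <- sample.int(length(universe), genes_per_signature)
    sig[picked[seq_len(n_up)]] <- 1L
    sig[picked[-seq_len(n_up)]] <- -1L
    protos[[k]] <- sig
  }
  drugs <- list(); class_of <- character(0)
  symbols <- c(-1L, 0L, 1L)
  for (k in seq_len(n_classes)) {
    for (d in seq_len(drugs_per_class)) {
      sig <- protos[[k]]
      flip <- stats::runif(length(sig)) < flip_rate
      if (any(flip)) {
        sig[flip] <- vapply(sig[flip], function(cur) {
          sample(setdiff(symbols, cur), 1)
        }, integer(1))
      }
      id <- sprintf("drug_c%02d_%02d", k, d)
      drugs[[id]] <- list(up = universe[sig == 1L], down = universe[sig == -1L])
      class_of[id] <- paste0("class", k)
    }
  }
  drug_signature_set(drugs, universe = universe, moa = class_of)
}
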