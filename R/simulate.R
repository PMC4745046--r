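## Synthetic-cohort generation from a known ground-truth two-slice
## conditional linear Gaussian model.
##
## The generator emulates the study design the analysis assumes: ~58
## preterm-infant subjects sampled every 1-2 days over their first weeks of
## life, three dominant taxa (Bacilli -> Gammaproteobacteria -> Clostridia
## succession) plus ~11 rare taxa at trace abundance, monotonically
## increasing age covariates, per-sample read depths drawn around a median
## of ~7000, and optional injected abruption events.  Latent compositions
## evolve by the linear truth model plus Gaussian residuals, are clipped to
## zero and renormalized to the simplex (the same rule used to normalize
## predictions), and counts are multinomial draws at the sampled depth.

PAPER_TAXA <- c("Actinobacteria", "Alphaproteobacteria", "Bacilli",
                "Bacteroidia", "Betaproteobacteria", "Clostridia",
                "Cyanobacteria", "Epsilonproteobacteria", "Erysipelotrichi",
                "Flavobacteria", "Fusobacteria", "Gammaproteobacteria",
                "Holophagae", "unclassified")
DOMINANT_TAXA <- c("Bacilli", "Clostridia", "Gammaproteobacteria")

#' Ground-truth transition model
#'
#' Defines the data-generating two-slice model: per-taxon intercepts, a
#' taxa-to-taxa coefficient matrix `W` (rows = children at t + 1, columns =
#' parents at t), a per-taxon post-conceptional-age coefficient (per week
#' above `pca_ref`), and per-taxon residual standard deviations.  The taxa
#' block must have spectral radius < 1 (stable dynamics) unless
#' `allow_unstable = TRUE`.
#'
#' @param taxa Taxon names.
#' @param intercepts,age_coef,sigma Numeric vectors (length = taxa).
#' @param W Square coefficient matrix with `taxa` dimnames.
#' @param dominant Names of the dominant taxa.
#' @param pca_ref Reference post-conceptional age (weeks).
#' @param init_shape Gamma shape parameters used to draw each subject's
#'   initial composition.
#' @param abruptions Optional data frame (`subject`, `step`, `mode`) of
#'   abruptions injected after generation.
#' @param allow_unstable Permit an unstable taxa block.
#' @return List of class `dbn_truth`.
#' @export
ground_truth <- function(taxa, intercepts, W, age_coef, sigma,
                         dominant = intersect(DOMINANT_TAXA, taxa),
                         pca_ref = 28, init_shape = NULL,
                         abruptions = NULL, allow_unstable = FALSE) {
  k <- length(taxa)
  stopifnot(length(intercepts) == k, length(age_coef) == k,
            length(sigma) == k, all(dim(W) == k), all(sigma > 0))
  dimnames(W) <- list(taxa, taxa)
  names(intercepts) <- names(age_coef) <- names(sigma) <- taxa
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho >= 1 && !allow_unstable) {
    stop(sprintf(paste0("unstable truth model: spectral radius %.3f >= 1 ",
                        "(set allow_unstable = TRUE to override)"), rho))
  }
  if (is.null(init_shape)) {
    init_shape <- stats::setNames(rep(0.2, k), taxa)
    init_shape[intersect(c("Bacilli", "Gammaproteobacteria", "Clostridia"),
                         taxa)] <- c(12, 5, 1)
  }
  structure(list(taxa = taxa, dominant = dominant,
                 intercepts = intercepts, W = W, age_coef = age_coef,
                 sigma = sigma, pca_ref = pca_ref,
                 init_shape = init_shape, abruptions = abruptions,
                 spectral_radius = rho),
            class = "dbn_truth")
}

#' Default succession ground truth
#'
#' A 14-taxon model reproducing the dominant-taxa succession: Bacilli start
#' high and are suppressed by infiltrating Clostridia (and by the rare
#' Actinobacteria), Gammaproteobacteria feed on declining Bacilli and rise
#' before giving way, and Clostridia grow with post-conceptional age (and
#' with prior Fusobacteria).  Rare taxa decay toward trace abundance.
#'
#' @return A [ground_truth()] object.
#' @export
default_truth <- function() {
  taxa <- PAPER_TAXA
  k <- length(taxa)
  W <- matrix(0, k, k, dimnames = list(taxa, taxa))
  a <- stats::setNames(rep(0.002, k), taxa)
  sg <- stats::setNames(rep(0.006, k), taxa)
  age <- stats::setNames(rep(0, k), taxa)
  for (t in taxa) W[t, t] <- 0.55
  W["Bacilli", "Bacilli"] <- 0.70
  W["Bacilli", "Clostridia"] <- -0.20
  W["Bacilli", "Actinobacteria"] <- -0.30
  # dominant-taxon residual scale ~0.08 keeps per-sample MAE near the
  # few-percent volatility seen in real preterm-infant cohorts
  a["Bacilli"] <- 0.05; sg["Bacilli"] <- 0.08
  W["Gammaproteobacteria", "Gammaproteobacteria"] <- 0.70
  W["Gammaproteobacteria", "Bacilli"] <- 0.25
  a["Gammaproteobacteria"] <- 0.05; sg["Gammaproteobacteria"] <- 0.08
  W["Clostridia", "Clostridia"] <- 0.75
  W["Clostridia", "Fusobacteria"] <- 0.30
  a["Clostridia"] <- 0.01; sg["Clostridia"] <- 0.08
  age["Clostridia"] <- 0.012
  W["Bacteroidia", "Bacteroidia"] <- 0.60
  W["Bacteroidia", "Actinobacteria"] <- 0.20
  ground_truth(taxa, a, W, age, sg)
}

#' Planted ground truth for structure-recovery experiments
#'
#' Builds an `n_taxa`-node model mirroring the cohort's common/rare
#' architecture: the first half are "common" taxa (larger fixed points,
#' autoregressive self-edges of standardized effect ~1.6) carrying all
#' `n_cross` planted cross edges; the second half are trace taxa with weak
#' self-dynamics (standardized effect < 0.5, below the evaluated-edge
#' threshold).  Cross edges run from lower to higher index (triangular,
#' hence stable) and are planted in `+beta`/`-beta` pairs sharing each
#' parent, so the common-block column sums are equal and the latent
#' normalizing sum barely depends on the parent composition.  Residual
#' scales are set to three stationary standard deviations below the fixed
#' points, keeping the clip-at-zero rate ~0.1%: without these two choices
#' the compositional observation layer (renormalization and clipping)
#' induces real dependencies that are not in the planted edge list, and
#' the list would not be the ground truth it claims to be.
#'
#' Cross-edge coefficients are sized so that the standardized effect
#' `|beta| * sd(parent) / sigma(child)` is approximately `effect`, using
#' the stationary AR approximation `sd = sigma / sqrt(1 - self^2)`.
#'
#' The default `n_cross = 4` keeps every true parent set strictly below
#' the sparse-regime cap of 3: when a child's true parents saturate the
#' cap, the greedy search can enter a correlated proxy first and then lack
#' room for the true parents, which tests the cap, not edge recovery.
#'
#' @param n_taxa Number of taxa nodes (even).
#' @param n_cross Number of planted cross edges (even; at most
#'   `2 * (n_taxa / 2 - 2)` placement slots are guaranteed).
#' @param effect Target standardized effect size of each cross edge.
#' @param self Self-edge coefficient of the common taxa.
#' @param seed Seed for the edge placement (not the cohort draw).
#' @return A [ground_truth()] object with attribute `planted_edges` -- the
#'   edges of standardized effect >= 0.5 (cross edges plus common-taxon
#'   self-edges) as a data frame (`parent`, `child`, `beta`; self-edges
#'   carry `beta = self`) -- and attribute `true_edges`, every nonzero
#'   entry of the coefficient matrix including the weak rare-taxon
#'   self-edges.
#' @export
planted_truth <- function(n_taxa = 12, n_cross = 4, effect = 0.55,
                          self = 0.85, seed = 1) {
  stopifnot(n_taxa >= 6, n_taxa %% 2 == 0, n_cross %% 2 == 0)
  taxa <- sprintf("Taxon%02d", seq_len(n_taxa))
  n_common <- n_taxa / 2
  common <- seq_len(n_common)
  rare <- (n_common + 1):n_taxa
  fp <- numeric(n_taxa)
  fp[common] <- 0.84 / n_common
  fp[rare] <- 0.16 / (n_taxa - n_common)
  self_rare <- 0.3
  # sd three stationary sds below the fixed point => clip rate ~0.1%
  sigma <- numeric(n_taxa)
  sigma[common] <- fp[common] / 3 * sqrt(1 - self^2)
  sigma[rare] <- fp[rare] / 3 * sqrt(1 - self_rare^2)
  W <- diag(c(rep(self, n_common), rep(self_rare, n_taxa - n_common)))
  dimnames(W) <- list(taxa, taxa)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_pairs <- n_cross / 2
  picked <- NULL
  for (attempt in seq_len(50)) {      # greedy placement can dead-end
    set.seed(seed + (attempt - 1L) * 1009L)
    child_load <- integer(n_common)
    picked <- NULL
    for (pa in sample(n_common - 2)) {
      # at most one cross parent per child: self + cross = 2 parents,
      # strictly below the sparse-regime cap of 3
      free <- which(common > pa & child_load < 1)
      if (length(free) < 2) next
      chs <- sample(free, 2)
      child_load[chs] <- child_load[chs] + 1L
      picked <- rbind(picked, cbind(pa, chs))
      if (nrow(picked) == n_cross) break
    }
    if (!is.null(picked) && nrow(picked) == n_cross) break
  }
  if (is.null(picked) || nrow(picked) < n_cross) {
    stop("could not place ", n_cross, " cross edges among ",
         n_common, " common taxa")
  }
  sd_x <- sigma[common[1]] / sqrt(1 - self^2)
  beta <- effect * sigma[common[1]] / sd_x
  signs <- rep(c(1, -1), n_pairs)
  cross <- data.frame(parent = taxa[picked[, 1]],
                      child = taxa[picked[, 2]],
                      beta = beta * signs)
  for (e in seq_len(nrow(cross))) {
    W[cross$child[e], cross$parent[e]] <- cross$beta[e]
  }
  a <- drop((diag(n_taxa) - W) %*% fp)   # fixed point exactly fp
  tr <- ground_truth(taxa, a, W, age_coef = rep(0, n_taxa),
                     sigma = sigma, dominant = character(0),
                     init_shape = stats::setNames(fp * 60, taxa))
  attr(tr, "planted_edges") <- rbind(
    cross,
    data.frame(parent = taxa[common], child = taxa[common], beta = self))
  nz <- which(W != 0, arr.ind = TRUE)
  attr(tr, "true_edges") <- data.frame(parent = taxa[nz[, 2]],
                                       child = taxa[nz[, 1]],
                                       beta = W[nz])
  tr
}

#' Cohort design specification
#'
#' @param n_subjects Number of subjects (default 58).
#' @param samples_range Min/max samples per subject (discrete uniform; the
#'   default 10-22 gives ~16 samples per subject, landing total cohort
#'   size near ~920 samples).
#' @param gap_probs Probabilities of a 1- or 2-day gap between samples.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (median anchored near 7000 reads).
#' @param dol_range First-sample day-of-life range.
#' @param ga_range Gestational-age-at-birth range (weeks).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 58, samples_range = c(10, 22),
                        gap_probs = c(0.5, 0.5),
                        depth_meanlog = log(7000), depth_sdlog = 0.4,
                        dol_range = c(3, 7), ga_range = c(24, 33)) {
  stopifnot(n_subjects >= 1, samples_range[1] >= 2,
            samples_range[2] >= samples_range[1],
            abs(sum(gap_probs) - 1) < 1e-8)
  structure(list(n_subjects = as.integer(n_subjects),
                 samples_range = as.integer(samples_range),
                 gap_probs = gap_probs, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, dol_range = dol_range,
                 ga_range = ga_range),
            class = "cohort_spec")
}

#' Simulate a synthetic cohort
#'
#' Per subject: draws covariates and an initial composition, advances the
#' latent composition through the truth model with Gaussian residuals
#' (clipped to zero and renormalized), and emits per-sample counts by a
#' multinomial draw at a log-normal read depth.  Fully reproducible under
#' `seed`; the latent compositions are archived in the `latent` attribute,
#' the raw linear step before clipping/renormalization in `latent_raw`
#' (exact for coefficient-recovery oracles; `NA` for first samples), and
#' the truth model in the `truth` attribute.
#'
#' @param truth A [ground_truth()] object.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A `dbn_cohort`.
#' @export
simulate_cohort <- function(truth = default_truth(), spec = cohort_spec(),
                            seed = 1) {
  stopifnot(inherits(truth, "dbn_truth"), inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  taxa <- truth$taxa
  k <- length(taxa)
  metas <- list(); count_rows <- list(); latents <- list()
  latents_raw <- list()   # linear step before clipping/renormalization
  subj_ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  for (si in seq_len(spec$n_subjects)) {
    n_s <- sample(spec$samples_range[1]:spec$samples_range[2], 1)
    ga <- round(stats::runif(1, spec$ga_range[1], spec$ga_range[2]), 1)
    dol <- sample(spec$dol_range[1]:spec$dol_range[2], 1)
    open_room <- sample(OPEN_ROOM_LEVELS, 1)
    abx_rate <- stats::runif(1, 0, 0.5)
    abx_days <- stats::rbinom(1, dol, abx_rate)
    p <- stats::rgamma(k, shape = truth$init_shape[taxa])
    p <- p / sum(p)
    for (t in seq_len(n_s)) {
      if (t > 1) {
        gap <- sample(c(1L, 2L), 1, prob = spec$gap_probs)
        dol <- dol + gap
        abx_days <- abx_days + stats::rbinom(1, gap, abx_rate)
        pca <- ga + dol / 7
        mu <- truth$intercepts + drop(truth$W %*% p) +
          truth$age_coef * (pca - truth$pca_ref)
        p_raw <- mu + stats::rnorm(k, 0, truth$sigma)
        p <- pmax(p_raw, 0)
        if (sum(p) <= 0) p <- rep(1 / k, k) else p <- p / sum(p)
      } else {
        p_raw <- rep(NA_real_, k)
      }
      depth <- max(500L, round(stats::rlnorm(1, spec$depth_meanlog,
                                             spec$depth_sdlog)))
      counts <- drop(stats::rmultinom(1, depth, p))
      metas[[length(metas) + 1L]] <- data.frame(
        subject_id = subj_ids[si], day_of_life = dol,
        gestational_age = ga, postconceptional_age = ga + dol / 7,
        antibiotics = 100 * abx_days / dol, open_room = open_room)
      count_rows[[length(count_rows) + 1L]] <- counts
      latents[[length(latents) + 1L]] <- p
      latents_raw[[length(latents_raw) + 1L]] <- p_raw
    }
  }
  meta <- do.call(rbind, metas)
  counts <- do.call(rbind, count_rows)
  colnames(counts) <- taxa
  cohort <- as_cohort(meta, counts)
  lat <- do.call(rbind, latents)
  lat_raw <- do.call(rbind, latents_raw)
  colnames(lat) <- colnames(lat_raw) <- taxa
  attr(cohort, "latent") <- lat
  attr(cohort, "latent_raw") <- lat_raw
  attr(cohort, "truth") <- truth
  attr(cohort, "seed") <- seed
  if (!is.null(truth$abruptions)) {
    for (i in seq_len(nrow(truth$abruptions))) {
      cohort <- inject_abruption(cohort,
                                 truth$abruptions$subject[i],
                                 truth$abruptions$step[i],
                                 truth$abruptions$mode[i])
    }
  }
  cohort
}

#' Inject an abruption event into a cohort
#'
#' Replaces the designated sample's composition: `replace-with-unclassified`
#' puts the whole read depth on the unclassified taxon,
#' `replace-with-rare-taxon` on `taxon` (default Bacteroidia, echoing the
#' majority-Bacteroidia transitions seen in real abruptions), and
#' `shuffle-composition` permutes the sample's counts across taxa.  All
#' other samples are untouched; the injection is recorded in the
#' `injections` attribute.
#'
#' @param cohort A `dbn_cohort`.
#' @param subject_id Subject identifier.
#' @param step Sample index within the subject's ordered sequence.
#' @param mode One of `"replace-with-unclassified"`,
#'   `"replace-with-rare-taxon"`, `"shuffle-composition"`.
#' @param taxon Target taxon for `replace-with-rare-taxon`.
#' @return The modified cohort.
#' @export
inject_abruption <- function(cohort, subject_id, step,
                             mode = c("replace-with-unclassified",
                                      "replace-with-rare-taxon",
                                      "shuffle-composition"),
                             taxon = "Bacteroidia") {
  mode <- match.arg(mode)
  rows <- which(cohort$meta$subject_id == subject_id)
  if (!length(rows)) stop("unknown subject: ", subject_id)
  if (step < 1 || step > length(rows)) {
    stop("subject ", subject_id, " has no sample ", step)
  }
  r <- rows[step]
  depth <- sum(cohort$counts[r, ])
  if (mode == "replace-with-unclassified") {
    if (!"unclassified" %in% cohort$taxa) stop("no unclassified taxon")
    cohort$counts[r, ] <- 0
    cohort$counts[r, "unclassified"] <- depth
  } else if (mode == "replace-with-rare-taxon") {
    if (!taxon %in% cohort$taxa) stop("unknown taxon: ", taxon)
    cohort$counts[r, ] <- 0
    cohort$counts[r, taxon] <- depth
  } else {
    cohort$counts[r, ] <- sample(cohort$counts[r, ])
  }
  inj <- data.frame(subject_id = subject_id, step = step, mode = mode,
                    row = r)
  attr(cohort, "injections") <- rbind(attr(cohort, "injections"), inj)
  cohort
}

#' Simulate transitions from a fitted model (null draws)
#'
#' Given parent-slice rows, draws child values from the fitted conditional
#' distributions (normal with the posterior-mean parameters for continuous
#' children, the Dirichlet-multinomial predictive for discrete children).
#' Used for null calibration of the abruption scan: data simulated from the
#' model itself should be flagged at no more than the nominal rate.
#'
#' @param fit A [fit_dbn()] result.
#' @param parents_df Parent-slice data frame (e.g. resampled rows of
#'   `transitions$parents`).
#' @param seed Integer seed.
#' @return A `dbn_transitions` whose children are simulated.
#' @export
simulate_from_fit <- function(fit, parents_df, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(parents_df)
  children <- list()
  mu_all <- predict_continuous(fit, parents_df)
  for (ch in names(fit$children)) {
    rec <- fit$children[[ch]]
    labels <- config_labels(parents_df, rec$dparents, rec$dlevels)
    if (rec$kind == "continuous") {
      mu <- mu_all[, ch]
      sig <- vapply(labels, function(u) sqrt(rec$params[[u]]$sigma2),
                    numeric(1))
      children[[ch]] <- stats::rnorm(n, mu, sig)
    } else {
      draw <- character(n)
      for (u in unique(labels)) {
        i <- which(labels == u)
        nz <- if (u %in% rownames(rec$counts)) rec$counts[u, ] else 0
        w <- rec$a_cell + nz
        draw[i] <- sample(rec$states, length(i), replace = TRUE,
                          prob = w / sum(w))
      }
      children[[ch]] <- factor(draw, levels = rec$states)
    }
  }
  structure(list(parents = parents_df,
                 children = as.data.frame(children),
                 subject = sprintf("null%05d", seq_len(n)),
                 gap_days = rep(1L, n),
                 target_day = seq_len(n),
                 taxa = fit$taxa),
            class = "dbn_transitions")
}
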