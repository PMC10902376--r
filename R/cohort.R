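#' Gene panel and pathway map defaults
#'
#' The default gene panel holds the 25 driver genes shared by the two targeted
#' NGS panels after excluding IDH1/IDH2 (IDH-wildtype inclusion criterion).
#' The pathway map assigns 13 of them to the five signalling pathways most
#' frequently altered in glioblastoma: RB1, P53, MAPK, PI3K and RTK.
#'
#' @return `gbm_genes()`: character vector of 25 gene symbols.
#'   `gbm_pathways()`: named list mapping pathway name to member genes, in the
#'   fixed column order RB1, P53, MAPK, PI3K, RTK.
#' @export
gbm_genes <- function() {
  c("ARID2", "ATRX", "BRAF", "CDKN2A", "CIC", "DNMT3A", "EGFR", "FGFR2",
    "FUBP1", "KDR", "KRAS", "MDM4", "MET", "NF1", "NOTCH2", "NTRK1",
    "PDGFRA", "PIK3CA", "PIK3R1", "PTEN", "PTPN11", "RB1", "SETD2",
    "SMARCB1", "TP53")
}

#' @rdname gbm_genes
#' @export
gbm_pathways <- function() {
  list(
    RB1  = c("RB1", "CDKN2A"),
    P53  = c("MDM4", "TP53"),
    MAPK = c("BRAF", "NF1"),
    PI3K = c("PTEN", "PIK3R1", "PIK3CA"),
    RTK  = c("FGFR2", "MET", "PDGFRA", "EGFR")
  )
}

#' Configuration for the synthetic partial multi-modal cohort
#'
#' Collects and validates every knob of the generator. Defaults emulate the
#' study conditions: three planted subtypes, availability fractions
#' 0.46 / 0.33 / 0.21 (both / imaging-only / genomics-only), subtype hazard
#' multipliers 1.0 / 0.725 / 0.586, and a 100-feature imaging view of which 12
#' features carry subtype signal.
#'
#' @param n_subjects number of subjects to simulate.
#' @param n_subtypes number of planted subtypes.
#' @param n_imaging_features total imaging features.
#' @param n_informative_features features carrying subtype mean shifts.
#' @param genes gene symbols for the mutation table.
#' @param pathway_map named list, pathway -> member genes (subset of `genes`).
#' @param frac_both,frac_imaging_only,frac_genomic_only availability-class
#'   proportions; must sum to 1.
#' @param subtype_separation mean shift (in SD units) that an informative
#'   feature exhibits in its associated subtype.
#' @param mutation_base_rate per-gene Bernoulli mutation rate.
#' @param mutation_boost rate multiplier applied to a pathway's member genes
#'   within that pathway's associated subtype (pathways cycle over subtypes).
#' @param cooccurrence_pairs list of `list(gene_a, gene_b, subtype, log_or)`
#'   entries; within the named subtype the pair is drawn jointly with the
#'   given log odds ratio added to independence.
#' @param subtype_hazards per-subtype hazard multipliers.
#' @param baseline_hazard exponential event rate (per month) at multiplier 1.
#' @param censoring_rate target fraction of censored subjects.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 500L,
                             n_subtypes = 3L,
                             n_imaging_features = 100L,
                             n_informative_features = 12L,
                             genes = gbm_genes(),
                             pathway_map = gbm_pathways(),
                             frac_both = 0.46,
                             frac_imaging_only = 0.33,
                             frac_genomic_only = 0.21,
                             subtype_separation = 2.0,
                             mutation_base_rate = 0.12,
                             mutation_boost = 4,
                             cooccurrence_pairs = default_cooccurrence_pairs(),
                             subtype_hazards = c(1.0, 0.725, 0.586),
                             baseline_hazard = 1 / 15,
                             censoring_rate = 0.30,
                             seed = 1L) {
  fr <- c(frac_both, frac_imaging_only, frac_genomic_only)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("availability fractions must sum to 1 (got ", sum(fr), ")")
  if (any(fr < 0)) stop("availability fractions must be non-negative")
  if (n_subjects < n_subtypes)
    stop("need at least as many subjects as subtypes")
  if (n_informative_features > n_imaging_features)
    stop("n_informative_features exceeds n_imaging_features")
  stopifnot(n_subjects >= 1, n_subtypes >= 1, n_imaging_features >= 1,
            subtype_separation >= 0, mutation_base_rate > 0,
            mutation_base_rate < 1, censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0)
  if (!all(unlist(pathway_map) %in% genes))
    stop("pathway_map contains genes absent from the gene panel: ",
         paste(setdiff(unlist(pathway_map), genes), collapse = ", "))
  if (length(subtype_hazards) != n_subtypes)
    stop("subtype_hazards must have one multiplier per subtype")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_subtypes = as.integer(n_subtypes),
    n_imaging_features = as.integer(n_imaging_features),
    n_informative_features = as.integer(n_informative_features),
    genes = genes, pathway_map = pathway_map,
    frac_both = frac_both, frac_imaging_only = frac_imaging_only,
    frac_genomic_only = frac_genomic_only,
    subtype_separation = subtype_separation,
    mutation_base_rate = mutation_base_rate,
    mutation_boost = mutation_boost,
    cooccurrence_pairs = cooccurrence_pairs,
    subtype_hazards = subtype_hazards,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_cooccurrence_pairs <- function() {
  list(
    list(gene_a = "TP53", gene_b = "RB1", subtype = 1L, log_or = log(6)),
    list(gene_a = "TP53", gene_b = "RB1", subtype = 2L, log_or = log(6)),
    list(gene_a = "TP53", gene_b = "RB1", subtype = 3L, log_or = log(6)),
    list(gene_a = "NOTCH2", gene_b = "MDM4", subtype = 1L, log_or = log(6))
  )
}

# joint success probability p11 for two Bernoulli margins with odds ratio psi
# (Plackett construction); psi = 1 reduces to independence.
joint_p11 <- function(pa, pb, psi) {
  if (abs(psi - 1) < 1e-12) return(pa * pb)
  s <- 1 + (pa + pb) * (psi - 1)
  (s - sqrt(s^2 - 4 * psi * (psi - 1) * pa * pb)) / (2 * (psi - 1))
}

# gene x subtype mutation probability matrix implied by a config
mutation_rate_matrix <- function(config) {
  rates <- matrix(config$mutation_base_rate,
                  nrow = length(config$genes), ncol = config$n_subtypes,
                  dimnames = list(config$genes, NULL))
  pw <- config$pathway_map
  for (p in seq_along(pw)) {
    st <- ((p - 1L) %% config$n_subtypes) + 1L
    rates[pw[[p]], st] <- pmin(0.9, rates[pw[[p]], st] * config$mutation_boost)
  }
  rates
}

#' Construct a partial multi-modal dataset
#'
#' Validates and bundles the two modality views. Rows of `imaging` and
#' `genomic` are aligned to `subject_ids`; a subject absent from a modality
#' has `NA` in that view's rows and `FALSE` in its mask.
#'
#' @param subject_ids character vector of unique identifiers.
#' @param imaging numeric matrix (subjects x features), `NA` rows where absent.
#' @param genomic binary matrix (subjects x genes), `NA` rows where absent.
#' @param has_imaging,has_genomic logical availability masks.
#' @param cohort_split character vector, `"discovery"` or `"replication"`.
#' @return object of class `partial_mm_dataset`.
#' @export
partial_mm_dataset <- function(subject_ids, imaging, genomic,
                               has_imaging, has_genomic, cohort_split) {
  n <- length(subject_ids)
  stopifnot(!anyDuplicated(subject_ids), nrow(imaging) == n,
            nrow(genomic) == n, length(has_imaging) == n,
            length(has_genomic) == n, length(cohort_split) == n)
  if (any(!has_imaging & !has_genomic))
    stop("subjects present in neither modality are not admissible: ",
         paste(subject_ids[!has_imaging & !has_genomic], collapse = ", "))
  gv <- genomic[has_genomic, , drop = FALSE]
  if (!all(gv %in% c(0, 1)))
    stop("genomic entries must be binary 0/1")
  if (any(is.na(imaging[has_imaging, , drop = FALSE])))
    stop("imaging mask inconsistent with stored rows (NA where present)")
  rownames(imaging) <- rownames(genomic) <- subject_ids
  structure(list(subject_ids = subject_ids, imaging = imaging,
                 genomic = genomic, has_imaging = has_imaging,
                 has_genomic = has_genomic, cohort_split = cohort_split),
            class = "partial_mm_dataset")
}

#' @export
print.partial_mm_dataset <- function(x, ...) {
  cat(sprintf(
    "partial_mm_dataset: %d subjects (%d both, %d imaging-only, %d genomic-only)\n",
    length(x$subject_ids), sum(x$has_imaging & x$has_genomic),
    sum(x$has_imaging & !x$has_genomic), sum(!x$has_imaging & x$has_genomic)))
  cat(sprintf("  imaging: %d features | genomic: %d genes\n",
              ncol(x$imaging), ncol(x$genomic)))
  invisible(x)
}

#' Generate a synthetic partial two-modality cohort
#'
#' Plants `n_subtypes` subtypes expressed in both views. Informative imaging
#' features are Gaussian with a `subtype_separation` mean shift in their
#' associated subtype (features cycle over subtypes); the rest are standard
#' Gaussian noise. Mutations are Bernoulli with subtype-modulated,
#' pathway-structured rates, with optional planted pairwise co-occurrence.
#' Overall survival is exponential with per-subtype proportional hazards and
#' independent uniform-window censoring calibrated to `censoring_rate`.
#' Availability classes and the 50/50 discovery/replication split are drawn at
#' random. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` ([partial_mm_dataset()]), `clinical`
#'   (data.frame: subject_id, os_time, event, age, sex, mgmt, eor, cohort),
#'   and `truth` (list: subtype_labels, informative_feature_ids,
#'   true_hazard_multipliers, mutation_rates).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_subtypes
  ids <- sprintf("S%04d", seq_len(n))
  subtype <- sample.int(k, n, replace = TRUE)

  # imaging: informative features get a +separation mean in their subtype
  p <- config$n_imaging_features
  m <- config$n_informative_features
  imaging <- matrix(stats::rnorm(n * p), n, p,
                    dimnames = list(ids, sprintf("feat_%03d", seq_len(p))))
  if (m > 0) {
    assoc <- ((seq_len(m) - 1L) %% k) + 1L   # feature j -> its subtype
    for (j in seq_len(m))
      imaging[, j] <- imaging[, j] +
        config$subtype_separation * (subtype == assoc[j])
  }

  # genomic: independent Bernoulli at subtype-specific rates, then planted
  # co-occurring pairs redrawn jointly within their target subtype
  rates <- mutation_rate_matrix(config)
  g <- length(config$genes)
  genomic <- matrix(0L, n, g, dimnames = list(ids, config$genes))
  for (j in seq_len(g))
    genomic[, j] <- stats::rbinom(n, 1L, rates[j, subtype])
  for (pair in config$cooccurrence_pairs) {
    st <- pair$subtype
    if (st > k) next
    idx <- which(subtype == st)
    if (!length(idx)) next
    pa <- rates[pair$gene_a, st]; pb <- rates[pair$gene_b, st]
    p11 <- joint_p11(pa, pb, exp(pair$log_or))
    probs <- c(p11, pa - p11, pb - p11, 1 - pa - pb + p11)
    cell <- sample.int(4L, length(idx), replace = TRUE, prob = probs)
    genomic[idx, pair$gene_a] <- as.integer(cell %in% c(1L, 2L))
    genomic[idx, pair$gene_b] <- as.integer(cell %in% c(1L, 3L))
  }

  # survival: exponential PH over subtype multipliers; uniform censoring
  # window solved so the marginal censoring fraction matches the target
  lam <- config$baseline_hazard * config$subtype_hazards[subtype]
  t_event <- stats::rexp(n, rate = lam)
  if (config$censoring_rate > 0) {
    w <- censoring_window(config)
    t_cens <- stats::runif(n, 0, w)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  age <- round(stats::rnorm(n, 63.7, 11.6), 1)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.61, 0.39))
  mgmt <- sample(c("methylated", "unmethylated", NA), n, replace = TRUE,
                 prob = c(0.22, 0.35, 0.43))
  eor <- sample(c("near/gross total", "partial/biopsy", NA), n, replace = TRUE,
                prob = c(0.55, 0.35, 0.10))
  cohort <- sample(rep(c("discovery", "replication"), length.out = n))

  avail <- sample(c("both", "imaging", "genomic"), n, replace = TRUE,
                  prob = c(config$frac_both, config$frac_imaging_only,
                           config$frac_genomic_only))
  has_img <- avail %in% c("both", "imaging")
  has_gen <- avail %in% c("both", "genomic")
  imaging[!has_img, ] <- NA_real_
  genomic[!has_gen, ] <- NA_integer_

  dataset <- partial_mm_dataset(ids, imaging, genomic, has_img, has_gen, cohort)
  clinical <- data.frame(subject_id = ids, os_time = os_time, event = event,
                         age = age, sex = sex, mgmt = mgmt, eor = eor,
                         cohort = cohort, stringsAsFactors = FALSE)
  truth <- list(subtype_labels = stats::setNames(subtype, ids),
                informative_feature_ids = seq_len(m),
                true_hazard_multipliers = config$subtype_hazards,
                mutation_rates = rates)
  list(dataset = dataset, clinical = clinical, truth = truth)
}

# width w of the Uniform(0, w) censoring window such that
# P(C < T) = censoring_rate under the subtype mixture of exponentials:
# P(C < T | lambda) = (1 - exp(-lambda w)) / (lambda w)
censoring_window <- function(config) {
  lams <- config$baseline_hazard * config$subtype_hazards
  target <- config$censoring_rate
  f <- function(w) mean((1 - exp(-lams * w)) / (lams * w)) - target
  stats::uniroot(f, c(1e-6, 1e6), tol = 1e-10)$root
}

#' Degrade a complete cohort to partial availability
#'
#' Reassigns availability classes at the given fractions, masking modality
#' rows accordingly; the underlying data and planted truth are untouched, so
#' clusterings before and after masking share the same ground truth.
#'
#' @param dataset a [partial_mm_dataset()] (typically fully observed).
#' @param frac_both,frac_imaging_only,frac_genomic_only target proportions.
#' @param seed RNG seed for the class assignment.
#' @return a new `partial_mm_dataset`.
#' @export
mask_availability <- function(dataset, frac_both = 0.46,
                              frac_imaging_only = 0.33,
                              frac_genomic_only = 0.21, seed = 1L) {
  if (abs(frac_both + frac_imaging_only + frac_genomic_only - 1) > 1e-9)
    stop("availability fractions must sum to 1")
  set.seed(seed)
  n <- length(dataset$subject_ids)
  avail <- sample(c("both", "imaging", "genomic"), n, replace = TRUE,
                  prob = c(frac_both, frac_imaging_only, frac_genomic_only))
  has_img <- dataset$has_imaging & avail %in% c("both", "imaging")
  has_gen <- dataset$has_genomic & avail %in% c("both", "genomic")
  # a subject losing its only modality keeps it (every subject stays observed)
  orphan <- !has_img & !has_gen
  has_img[orphan] <- dataset$has_imaging[orphan]
  has_gen[orphan & !has_img] <- dataset$has_genomic[orphan & !has_img]
  imaging <- dataset$imaging; imaging[!has_img, ] <- NA_real_
  genomic <- dataset$genomic; genomic[!has_gen, ] <- NA_integer_
  partial_mm_dataset(dataset$subject_ids, imaging, genomic, has_img, has_gen,
                     dataset$cohort_split)
}

#' Collapse gene mutations to pathway alteration labels
#'
#' A pathway is altered in a subject iff any member gene is mutated
#' (logical OR). Columns follow the order of `pathway_map` (default RB1, P53,
#' MAPK, PI3K, RTK).
#'
#' @param genomic binary subjects x genes matrix (gene symbols as colnames).
#' @param pathway_map named list, pathway -> member genes.
#' @return binary subjects x pathways matrix.
#' @export
derive_pathway_labels <- function(genomic, pathway_map = gbm_pathways()) {
  missing <- setdiff(unlist(pathway_map), colnames(genomic))
  if (length(missing))
    stop("gene(s) missing from mutation table: ",
         paste(missing, collapse = ", "))
  out <- vapply(pathway_map, function(gs) {
    as.integer(rowSums(genomic[, gs, drop = FALSE]) > 0)
  }, integer(nrow(genomic)))
  out <- matrix(out, nrow = nrow(genomic),
                dimnames = list(rownames(genomic), names(pathway_map)))
  out
}
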