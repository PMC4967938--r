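# Synthetic two-class expression data with known pathway-level ground
# truth. Emulates the statistical structure the concordance analysis
# assumes: per-gene baseline intensities on a log2-like scale with Gaussian
# noise, and coherent mean shifts of pathway members between the disease
# and control groups. Effects are expressed in per-gene SD units so
# recovery thresholds are scale-free. No probe-level structure is
# simulated; the collapse module is tested with its own fixtures.

#' Simulation design for synthetic expression studies
#'
#' Defaults describe the reference study condition used throughout the
#' package's validation: 1,000 genes, 20 disjoint sets of 30 genes,
#' 10 case vs 10 control samples, an effect size of 2 noise-SD units, and
#' 2 upregulated plus 2 downregulated pathways per model — a 10% base rate
#' of calls per direction, the rate used in the worked chance-expectation
#' example of [chance_expectation].
#'
#' @param n_genes size of the gene universe.
#' @param n_sets number of gene sets.
#' @param set_size members per set.
#' @param set_overlap fraction of members shared between adjacent sets
#'   (0 = disjoint sets).
#' @param n_case,n_control samples per class (>= 2 each).
#' @param delta effect size: mean shift of regulated-set members in case
#'   samples, in units of the per-gene noise SD (>= 0; 0 = null data).
#' @param sigma per-gene noise SD (scalar, or length \code{n_genes}).
#' @param n_up,n_down number of truly up-/down-regulated sets per model.
#' @param rho cross-model overlap: fraction of model A's regulated sets
#'   shared (same direction) by model B in [simulate_model_pair].
#' @param seed integer RNG seed.
#' @return list of class \code{"sim_design"}.
#' @export
simulation_design <- function(n_genes = 1000L, n_sets = 20L, set_size = 30L,
                              set_overlap = 0, n_case = 10L,
                              n_control = 10L, delta = 2, sigma = 1,
                              n_up = 2L, n_down = 2L, rho = 0.5,
                              seed = NULL) {
  stopifnot(n_genes >= set_size, set_overlap >= 0, set_overlap < 1,
            n_case >= 2L, n_control >= 2L, delta >= 0, all(sigma > 0),
            n_up + n_down <= n_sets, rho >= 0, rho <= 1)
  structure(list(n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 set_size = as.integer(set_size), set_overlap = set_overlap,
                 n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 delta = delta, sigma = sigma,
                 n_up = as.integer(n_up),
                 n_down = as.integer(n_down),
                 rho = rho, seed = seed),
            class = "sim_design")
}

#' Generate the gene universe and gene-set layout of a design
#'
#' Sets are drawn without replacement from the gene universe. With
#' \code{set_overlap = 0} the sets are disjoint by construction (an error
#' if infeasible); with a positive overlap each set shares
#' \code{round(set_overlap * set_size)} members with its predecessor.
#'
#' @param design a [simulation_design].
#' @return a [gene_sets] collection (GMT-writable) over genes
#'   \code{g0001...}.
#' @export
make_gene_sets <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  k <- round(design$set_overlap * design$set_size)
  fresh_per_set <- c(design$set_size,
                     rep(design$set_size - k, design$n_sets - 1L))
  if (sum(fresh_per_set) > design$n_genes)
    stop("infeasible layout: ", sum(fresh_per_set),
         " distinct member slots needed but only ", design$n_genes,
         " genes in the universe")
  genes <- sprintf("g%04d", seq_len(design$n_genes))
  .with_seed(design$seed, {
    pool <- sample(genes)  # random disjoint allocation
    sets <- vector("list", design$n_sets)
    used <- 0L
    for (i in seq_len(design$n_sets)) {
      fresh <- pool[used + seq_len(fresh_per_set[i])]
      used <- used + fresh_per_set[i]
      shared <- if (i > 1L && k > 0L) sample(sets[[i - 1L]], k)
                else character(0)
      sets[[i]] <- sample(c(shared, fresh))
    }
    names(sets) <- sprintf("SET_%02d", seq_len(design$n_sets))
    gene_sets(sets, rep("synthetic pathway", design$n_sets))
  })
}

# additive case-group shift per gene for a given truth assignment; genes in
# sets of both directions cancel (logged)
.truth_shift <- function(sets, truth, genes, delta, sigma_g) {
  up_genes <- unique(unlist(unclass(sets)[truth$up], use.names = FALSE))
  down_genes <- unique(unlist(unclass(sets)[truth$down], use.names = FALSE))
  both <- intersect(up_genes, down_genes)
  if (length(both))
    message(length(both),
            " gene(s) in sets of both directions; shifts cancel")
  shift <- numeric(length(genes))
  names(shift) <- genes
  shift[setdiff(up_genes, both)] <- delta
  shift[setdiff(down_genes, both)] <- -delta
  shift * sigma_g
}

#' Simulate one two-class dataset with planted pathway regulation
#'
#' Gene g in sample s has value \eqn{\mu_g + \epsilon}, with baseline
#' \eqn{\mu_g \sim N(8, 2)} on the log2-like intensity scale and
#' \eqn{\epsilon \sim N(0, \sigma_g)}. Members of an upregulated set gain
#' \eqn{+\delta \sigma_g} in case samples, members of a downregulated set
#' \eqn{-\delta \sigma_g}; a gene in sets of both directions has the
#' shifts cancel (logged). With \code{delta = 0} case and control are
#' exchangeable.
#'
#' @param design a [simulation_design].
#' @param truth list with \code{up} and \code{down}: disjoint character
#'   vectors of regulated set names. Default: the first \code{n_up} and
#'   next \code{n_down} sets.
#' @param sets optional pre-built [gene_sets] from [make_gene_sets] (so a
#'   dataset pair can share one layout).
#' @param seed RNG seed for the noise (default \code{design$seed}).
#' @param id dataset id recorded in the truth record.
#' @return list with \code{dataset} ([expression_dataset]), \code{sets},
#'   \code{truth} (list up/down), \code{id}.
#' @export
simulate_dataset <- function(design, truth = NULL, sets = NULL,
                             seed = design$seed, id = "sim") {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(sets)) sets <- make_gene_sets(design)
  if (is.null(truth))
    truth <- list(up = names(sets)[seq_len(design$n_up)],
                  down = names(sets)[design$n_up + seq_len(design$n_down)])
  stopifnot(all(c(truth$up, truth$down) %in% names(sets)),
            length(intersect(truth$up, truth$down)) == 0L)
  genes <- sprintf("g%04d", seq_len(design$n_genes))
  sigma_g <- rep(design$sigma, length.out = design$n_genes)
  n_s <- design$n_control + design$n_case
  phen <- rep(c("control", "disease"),
              c(design$n_control, design$n_case))
  shift <- .truth_shift(sets, truth, genes, design$delta, sigma_g)
  vals <- .with_seed(seed, {
    mu <- stats::rnorm(design$n_genes, 8, 2)
    eps <- matrix(stats::rnorm(design$n_genes * n_s, 0, sigma_g),
                  design$n_genes, n_s)
    m <- mu + eps
    m[, phen == "disease"] <- m[, phen == "disease"] + shift
    m
  })
  dimnames(vals) <- list(genes, sprintf("%s_s%02d", id, seq_len(n_s)))
  list(dataset = expression_dataset(vals, phen, case = "disease",
                                    scale_note = "log2-like synthetic"),
       sets = sets, truth = truth, id = id)
}

# designed three-state profile implied by a truth assignment
.truth_profile <- function(truth, set_names, id) {
  state <- rep("null", length(set_names))
  state[set_names %in% truth$up] <- "up"
  state[set_names %in% truth$down] <- "down"
  structure(data.frame(pathway = set_names,
                       state = factor(state, levels = c("up", "down", "null")),
                       NES = NA_real_, q = NA_real_,
                       stringsAsFactors = FALSE),
            id = id, fdr_threshold = NA_real_,
            class = c("pathway_profile", "data.frame"))
}

#' Simulate a pair of models with controlled pathway-truth overlap
#'
#' Model A receives \code{n_up} up- and \code{n_down} down-regulated sets.
#' Model B shares a fraction \code{rho} of A's regulated sets (same
#' direction) and draws the remainder from sets unregulated in A. The
#' shared count is \code{round(rho * (n_up + n_down))}, allocated to the up
#' direction first, so that the designed-profile mean predictive value
#' between the two truths equals \code{rho} exactly whenever
#' \code{rho * (n_up + n_down)} is integral (and the per-direction PPV and
#' NPV each equal \code{rho} whenever \code{rho * n_up} is); non-integral
#' counts are rounded with a message.
#'
#' @param design a [simulation_design].
#' @param rho overlap fraction in [0, 1] (default \code{design$rho}).
#' @return list with \code{dataset_A}, \code{dataset_B}
#'   ([expression_dataset]s over one shared gene-set layout), \code{sets},
#'   \code{truth_A}, \code{truth_B}, and designed [pathway_states]-style
#'   profiles \code{profile_A}, \code{profile_B}.
#' @export
simulate_model_pair <- function(design, rho = design$rho) {
  stopifnot(inherits(design, "sim_design"), rho >= 0, rho <= 1)
  sets <- make_gene_sets(design)
  nm <- names(sets)
  n_up <- design$n_up; n_down <- design$n_down
  k_total <- round(rho * (n_up + n_down))
  if (abs(k_total - rho * (n_up + n_down)) > 1e-9)
    message("rho * (n_up + n_down) not integral; shared count rounded to ",
            k_total)
  k_up <- min(n_up, ceiling(k_total / 2))
  k_down <- min(n_down, k_total - k_up)
  k_up <- k_total - k_down  # spill back if n_down capped the down share
  stopifnot(k_up <= n_up)
  .with_seed(if (is.null(design$seed)) NULL else design$seed + 1000L, {
    reg_A <- sample(nm, n_up + n_down)
    truth_A <- list(up = reg_A[seq_len(n_up)],
                    down = reg_A[n_up + seq_len(n_down)])
    free <- setdiff(nm, reg_A)
    need <- (n_up - k_up) + (n_down - k_down)
    if (length(free) < need)
      stop("not enough unregulated sets for the non-shared remainder (",
           length(free), " free, ", need, " needed)")
    novel <- sample(free, need)
    truth_B <- list(
      up = c(sample(truth_A$up, k_up), novel[seq_len(n_up - k_up)]),
      down = c(sample(truth_A$down, k_down),
               novel[(n_up - k_up) + seq_len(n_down - k_down)]))
    seed_A <- if (is.null(design$seed)) NULL else design$seed + 2000L
    seed_B <- if (is.null(design$seed)) NULL else design$seed + 3000L
    a <- simulate_dataset(design, truth_A, sets, seed = seed_A, id = "A")
    b <- simulate_dataset(design, truth_B, sets, seed = seed_B, id = "B")
    list(dataset_A = a$dataset, dataset_B = b$dataset, sets = sets,
         truth_A = truth_A, truth_B = truth_B,
         profile_A = .truth_profile(truth_A, nm, "A"),
         profile_B = .truth_profile(truth_B, nm, "B"))
  })
}
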