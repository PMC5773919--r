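# Forward-sampling generator: plants a block membership structure and draws
# both network layers from the model's own Bernoulli exponential link, so
# every downstream module can be exercised without external data.

#' Describe a planted simulation design
#'
#' Parameters of a synthetic instance with known ground truth. Proteins are
#' split into `n_clusters` roughly equal planted complexes; a fraction
#' `overlap_fraction` of proteins additionally joins a second complex. Each
#' planted membership entry has value `membership_strength`, so a pair
#' sharing one complex interacts with probability
#' `1 - exp(-membership_strength^2)` (about 0.98 at the default strength 2).
#' Domains attach to proteins at random with `domains_per_protein` expected
#' associations per protein, and the domain network is drawn from the
#' induced domain memberships `F %*% H`, exactly as the model assumes.
#' After sampling, each non-edge is flipped to an edge with probability
#' `background_edge_noise` in both layers.
#'
#' @param n_proteins,n_domains,n_clusters counts (defaults 100, 40, 5).
#' @param membership_strength planted membership value (default 2).
#' @param overlap_fraction fraction of proteins in two complexes
#'   (default 0.1).
#' @param domains_per_protein expected associations per protein (default 2).
#' @param background_edge_noise spurious-edge probability (default 0.01).
#' @param seed RNG seed (default 1).
#' @return A list of class `planted_design`.
#' @export
planted_design <- function(n_proteins = 100, n_domains = 40, n_clusters = 5,
                           membership_strength = 2, overlap_fraction = 0.1,
                           domains_per_protein = 2,
                           background_edge_noise = 0.01, seed = 1) {
  stopifnot(n_proteins >= 1, n_domains >= 1, n_clusters >= 1,
            n_clusters <= n_proteins, membership_strength > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            domains_per_protein > 0,
            background_edge_noise >= 0, background_edge_noise <= 1)
  structure(list(n_proteins = n_proteins, n_domains = n_domains,
                 n_clusters = n_clusters,
                 membership_strength = membership_strength,
                 overlap_fraction = overlap_fraction,
                 domains_per_protein = domains_per_protein,
                 background_edge_noise = background_edge_noise,
                 seed = seed),
            class = "planted_design")
}

# Symmetric Bernoulli draw from the co-cluster affinity of H, with
# spurious-edge noise on the non-edges; zero diagonal.
sample_layer <- function(H, noise) {
  n <- nrow(H)
  W <- co_cluster_affinity(H)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- stats::rbinom(sum(up), 1, W[up])
  if (noise > 0) {
    flip <- up & A == 0
    A[flip] <- stats::rbinom(sum(flip), 1, noise)
  }
  A + t(A)
}

#' Sample a synthetic multi-network instance
#'
#' Draws one complete instance from a [planted_design()]: the true
#' membership matrix, the protein and domain interaction networks sampled
#' from the model, the domain-protein association map, the reference
#' catalog (planted complexes with at least three members), and an
#' annotation table in which each planted complex doubles as a functional
#' term. Fully reproducible from the design seed.
#'
#' @param design a [planted_design()].
#' @return List with elements `ppi`, `ddi` ([interaction_network]s),
#'   `associations` ([association_map]), `H_true`, `reference`
#'   ([complex_catalog]), `annotations` (named list term -> proteins), and
#'   `design`.
#' @examples
#' sim <- sample_instance(planted_design(n_proteins = 30, n_domains = 12,
#'                                       n_clusters = 3, seed = 7))
#' sim$ppi
#' @export
sample_instance <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(design$seed)
  n1 <- design$n_proteins
  n2 <- design$n_domains
  K <- design$n_clusters
  protein_ids <- sprintf("P%03d", seq_len(n1))
  domain_ids <- sprintf("D%03d", seq_len(n2))

  primary <- rep(seq_len(K), length.out = n1)
  H <- matrix(0, n1, K, dimnames = list(protein_ids, paste0("K", seq_len(K))))
  H[cbind(seq_len(n1), primary)] <- design$membership_strength
  n_over <- round(design$overlap_fraction * n1)
  if (n_over > 0 && K > 1) {
    overlapping <- sample.int(n1, n_over)
    second <- vapply(primary[overlapping], function(k)
      sample(setdiff(seq_len(K), k), 1), 0L)
    H[cbind(overlapping, second)] <- design$membership_strength
  }

  Fm <- matrix(stats::rbinom(n2 * n1, 1,
                             min(design$domains_per_protein / n2, 1)),
               n2, n1, dimnames = list(domain_ids, protein_ids))

  A1 <- sample_layer(H, design$background_edge_noise)
  A2 <- sample_layer(Fm %*% H, design$background_edge_noise)
  if (sum(A1) == 0 || sum(A2) == 0)
    stop("design produced an empty network; increase size, strength or noise")

  clusters <- lapply(seq_len(K), function(k) protein_ids[H[, k] > 0])
  names(clusters) <- sprintf("planted_%d", seq_len(K))
  reference <- complex_catalog(clusters[lengths(clusters) >= 3])
  annotations <- clusters
  names(annotations) <- sprintf("term_%d", seq_len(K))

  list(ppi = interaction_network(A1, protein_ids, "protein"),
       ddi = interaction_network(A2, domain_ids, "domain"),
       associations = association_map(Fm, domain_ids, protein_ids),
       H_true = H,
       reference = reference,
       annotations = annotations,
       design = design)
}
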