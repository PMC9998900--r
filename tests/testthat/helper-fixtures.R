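# shared fixtures, all built in code

# the 4-taxon reference tree used throughout the alpha/beta tests
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:2):0.5);")
}

# trait table of 5 traits over a small pool; heights span a known range
toy_traits <- function() {
  df <- data.frame(
    dispersal_type = c("wind", "water", "wind", "animal"),
    growth_form = c("forb", "forb", "graminoid", "forb"),
    life_cycle = c("annual", "annual", "perennial", "annual"),
    shoot_height = c(0.5, 1.0, 2.0, 0.5),
    flowering_phenology = c(5, 6, 8, 5),
    row.names = c("A", "B", "C", "D"), stringsAsFactors = FALSE)
  trait_table(df, c(dispersal_type = "categorical",
                    growth_form = "categorical",
                    life_cycle = "categorical",
                    shoot_height = "continuous",
                    flowering_phenology = "ordinal"))
}

# random symmetric distance matrix with unit-interval entries
rand_dist <- function(n, seed = 1, labels = sprintf("t%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# presence community matrix from a list of species vectors
make_comm <- function(site_species, species_pool) {
  C <- t(vapply(site_species, function(s) species_pool %in% s,
                logical(length(species_pool)))) * 1
  dimnames(C) <- list(names(site_species), species_pool)
  community_matrix(C, mode = "presence")
}

write_tmp_csv <- function(df, ext = ".csv") {
  f <- tempfile(fileext = ext)
  utils::write.csv(df, f, row.names = FALSE)
  f
}
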