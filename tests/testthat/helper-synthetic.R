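# Shared small-scale synthetic fixtures, built once per test run.
# Kept deliberately smaller than the package defaults so unit tests stay fast;
# the acceptance tests use full default sizes.

small_mesh <- function(seed = 11L) make_embryo_mesh(250, 100, seed = seed)

small_fields <- function(mesh, seed = 12L)
  make_expression_fields(mesh, default_marker_panel(100),
                         n_background = 200, n_smooth = 40, seed = seed)

# cached tiny atlas for the tests that need a full mapping context
.small_atlas_cache <- new.env(parent = emptyenv())
small_atlas <- function() {
  if (is.null(.small_atlas_cache$atlas))
    .small_atlas_cache$atlas <- build_synthetic_atlas(
      seed = 21, n_vertices = 250, n_background = 250, n_smooth = 50,
      samples_per_region = 6, cca_top_k = 150, cells_per_archetype = 100)
  .small_atlas_cache$atlas
}

# tiny deterministic count matrix for expr_io tests
toy_gene_expr <- function(n_genes = 5, n_cells = 4, seed = 3L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_cells, 20), n_genes, n_cells,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("c%02d", seq_len(n_cells))))
  })
  gene_expr(m, data.frame(condition = rep(c("A", "B"), length.out = n_cells),
                          row.names = colnames(m)))
}

# a straight-line "mesh" embedding for 1D GP toys: vertices on the x axis
line_mesh <- function(xs) {
  n <- length(xs)
  structure(list(vertices = cbind(xs, 0, 0),
                 faces = cbind(seq_len(n - 2), seq_len(n - 2) + 1,
                               seq_len(n - 2) + 2),
                 region = rep("EmDisc_anterior", n),
                 polar = rep(0, n), stage = "CS6"),
            class = "embryo_mesh")
}
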