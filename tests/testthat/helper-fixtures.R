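# in-code fixtures shared across test files

# small expression matrix with named cells/genes and type labels
toy_expression <- function() {
  values <- matrix(c(2, 0, 1, 3,
                     0, 3, 2, 0,
                     1, 1, 0, 2),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"),
                                   c("L1", "R1", "L2", "R2")))
  expression_matrix(values, cell_types = c("fibro", "macro", "fibro"))
}

toy_db <- function() lr_database(c("L1", "L2"), c("R1", "R2"))

# random raw CCIM with no zero-variance columns
random_ccim <- function(n = 20, p = 10, seed = 1) {
  set.seed(seed)
  scores <- matrix(abs(rnorm(n * p)), n, p)
  pairs <- data.frame(sender_id = sprintf("s%d", 1:n),
                      receiver_id = sprintf("r%d", 1:n),
                      sender_type = rep(c("t1", "t2"), length.out = n),
                      receiver_type = rep(c("t2", "t1"), length.out = n),
                      stringsAsFactors = FALSE)
  features <- data.frame(ligand = sprintf("L%d", 1:p),
                         receptor = sprintf("R%d", 1:p),
                         stringsAsFactors = FALSE)
  ccim(scores, pairs, features)
}

# standardized design matrix (population SD 1, mean 0 per column)
random_design <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  sweep(X, 2, sqrt(colMeans(X^2)), "/")
}
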