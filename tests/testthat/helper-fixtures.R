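# In-code fixtures: every table is built programmatically at test time.

# A tiny hand-checkable raw abundance table (values are powers of 2 so log2
# coordinates are integers).
tiny_table <- function() {
  donors <- c("d1", "d2", "d3")
  conditions <- c("ctrl", "doped")
  vals <- rbind(
    c(2, 4, 8, 16, 32, 64),
    c(8, 8, 8, 8, 8, 8),
    c(1, 2, 4, 1024, 2048, 4096))
  dimnames(vals) <- list(c("P04264", "P13645", "Q9P2E9"),
                         c("d1:ctrl", "d2:ctrl", "d3:ctrl",
                           "d1:doped", "d2:doped", "d3:doped"))
  abundance_table(vals,
                  data.frame(accession = rownames(vals),
                             gene = c("KRT1", "KRT10", "RRBP1"),
                             name = c("Keratin 1", "Keratin 10",
                                      "Ribosome-binding protein 1"),
                             stringsAsFactors = FALSE),
                  donors = donors, conditions = conditions)
}

# Random valid table for round-trip fuzzing.
random_table <- function(n = 5, donors = c("a", "b"),
                         conditions = c("x", "y", "z"), seed = 1) {
  set.seed(seed)
  keys <- as.vector(vapply(conditions,
                           function(cc) paste(donors, cc, sep = ":"),
                           character(length(donors))))
  vals <- matrix(exp(rnorm(n * length(keys), 10, 3)), nrow = n,
                 dimnames = list(sprintf("ACC%03d", seq_len(n)), keys))
  abundance_table(vals,
                  data.frame(accession = rownames(vals),
                             gene = sprintf("g%d", seq_len(n)),
                             name = sprintf("protein %d", seq_len(n)),
                             stringsAsFactors = FALSE),
                  donors = donors, conditions = conditions)
}

# Two well-separated Gaussian blobs in 3D as a donor_points frame.
two_blob_points <- function(n1 = 60, n2 = 60, gap = 20, sd = 0.5, seed = 1) {
  set.seed(seed)
  coords <- rbind(
    matrix(rnorm(n1 * 3, 0, sd), ncol = 3),
    matrix(rnorm(n2 * 3, gap, sd), ncol = 3))
  as_points(coords)
}

# Wrap a coordinate matrix as a donor_points frame (one pseudo-condition).
as_points <- function(coords, condition = "c1") {
  colnames(coords) <- paste0("D", seq_len(ncol(coords)))
  out <- data.frame(accession = sprintf("A%04d", seq_len(nrow(coords))),
                    condition = condition, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(coords))
  attr(out, "donors") <- colnames(coords)
  class(out) <- c("donor_points", "data.frame")
  out
}
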