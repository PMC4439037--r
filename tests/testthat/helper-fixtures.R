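# fixture builders shared across test files

# CA-only chain with an arbitrary one-letter sequence, gently curved so the
# coordinates are non-degenerate
seq_chain <- function(seq1, chain = "A", first_resno = 1) {
  res3 <- bio3d::aa123(strsplit(seq1, "")[[1]])
  n <- length(res3)
  k <- seq_len(n) - 1
  atoms <- data.frame(chain = chain, resno = first_resno + k, icode = "",
                      resid = res3, elety = "CA", elesy = "C",
                      x = 3.8 * k, y = 2 * sin(0.4 * k), z = 1.5 * cos(0.3 * k),
                      o = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
  ephcompare:::new_structure("seqchain", atoms)
}

# minimal mmCIF text for an eph_structure (atom_site loop only); lets the
# cross-format reader agreement be checked on fixtures the package emits
write_mmcif <- function(s, path) {
  a <- s$atoms
  lines <- c(
    paste0("data_", s$id),
    "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
                            "label_alt_id", "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "auth_seq_id", "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$elesy,
            a$elety, a$resid, a$chain, a$resno,
            ifelse(a$icode == "", "?", a$icode), a$x, a$y, a$z, a$o, a$b,
            a$resno, a$resid, a$chain, a$elety))
  writeLines(lines, path)
  path
}

# a small docked pair of sphere clusters used for interface-area properties
docked_clusters <- function(gap = 1.0, seed = 3) {
  set.seed(seed)
  a <- matrix(stats::runif(3 * 12, 0, 6), ncol = 3)
  b <- matrix(stats::runif(3 * 12, 0, 6), ncol = 3)
  b[, 1] <- b[, 1] + 6 + gap
  list(a = make_sphere_cluster(a, 1.7, chain = "A"),
       b = make_sphere_cluster(b, 1.7, chain = "B"))
}

protein_atom <- function(chain, resno, resid, elety, elesy, x, y = 0, z = 0) {
  data.frame(chain = chain, resno = resno, icode = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             o = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
}

mini_structure <- function(...) {
  ephcompare:::new_structure("toy", do.call(rbind, list(...)))
}
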