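# Independent oracles and tiny fixture builders used across the suite.
# These deliberately re-derive results by brute force or closed form,
# never by calling the code paths they check.

# --- brute-force Daura/GROMOS clustering ------------------------------------
# Straightforward transliteration of the published algorithm, recomputing
# the neighbor lists from scratch every round.
daura_brute <- function(m, cutoff) {
  n <- nrow(m)
  left <- seq_len(n)
  out <- list()
  while (length(left)) {
    best <- NA
    best_nb <- NULL
    for (i in left) {
      nb <- left[m[i, left] <= cutoff]
      if (is.null(best_nb) || length(nb) > length(best_nb)) {
        best <- i
        best_nb <- nb
      }
    }
    out[[length(out) + 1L]] <- list(center = best, members = sort(best_nb))
    left <- setdiff(left, best_nb)
  }
  sizes <- sapply(out, function(x) length(x$members))
  centers <- sapply(out, `[[`, "center")
  out[order(-sizes, centers)]
}

# random valid RMSD matrix: euclidean distances of random points (symmetric,
# zero diagonal, triangle inequality holds)
random_rmsd_matrix <- function(n, scale = 0.5) {
  pts <- matrix(runif(n * 3, 0, scale), ncol = 3)
  as.matrix(dist(pts))
}

# --- closed-form sphere areas -----------------------------------------------
# Exposed area of expanded sphere 1 (radius R1) partially occluded by
# expanded sphere 2 (radius R2) at center distance d: the spherical cap cut
# off by the radical plane is removed.
two_sphere_exposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  if (d + R1 <= R2) return(0)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# --- brute-force stretch enumeration ----------------------------------------
# Maximal single-gap stretches over a set of present residue numbers,
# enumerated by scanning every candidate start/end.
stretches_brute <- function(present) {
  present <- sort(unique(present))
  ok_span <- function(s, e) {
    span <- seq(s, e)
    miss <- setdiff(span, present)
    if (s %in% miss || e %in% miss) return(FALSE)
    # no two consecutive missing residues
    !any(diff(sort(miss)) == 1L) || length(miss) < 2L
  }
  res <- list()
  for (s in present) {
    e_best <- NA
    for (e in present[present >= s]) if (ok_span(s, e)) e_best <- e
    res[[length(res) + 1L]] <- c(s, e_best)
  }
  # keep only maximal (not contained in another)
  res <- unique(res)
  keep <- vapply(res, function(r)
    !any(vapply(res, function(q)
      (q[1] < r[1] && q[2] >= r[2]) || (q[1] <= r[1] && q[2] > r[2]),
      logical(1))), logical(1))
  res[keep]
}

# --- misc --------------------------------------------------------------------
single_atom_structure <- function(element = "C", x = 0, y = 0, z = 0,
                                  resname = "ALA", resno = 1L,
                                  chain = "A", name = element,
                                  serial = 1L) {
  data.frame(serial = serial, name = name, altloc = "", resname = resname,
             chain = chain, resno = as.integer(resno), icode = "",
             x = x, y = y, z = z, occupancy = 1, bscore = 0,
             element = element, stringsAsFactors = FALSE)
}

atoms_structure <- function(atom_df, id = "fixture") {
  atom_df$serial <- seq_len(nrow(atom_df))
  new("ProteinStructure", id = id, atoms = atom_df, title = "")
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, x, y, z, occ, b, element)
}

fixture_tables_path <- function(name)
  system.file("extdata", "tables", name, package = "boomdock")

read_bundled_lists <- function() {
  c(readResidueLists(fixture_tables_path("interfacial_residues_fragment1.txt")),
    readResidueLists(fixture_tables_path("interfacial_residues_fragment2.txt")))
}
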