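# Shared fixtures: the 20 four-variable BN general-graph representatives
# (labels A,B,C,D assigned left-to-right, top-to-bottom), with their expected
# extended notation, factorization terms and compact independence lists.
# BN10's published distribution omits the isolated p(A) term; the expected
# terms here include it.  BN14's published independence basis is one of two
# equally minimal ones; `ind_alt` records the convention this package
# produces (identical elementary closure, same size).

bn_rep_rows <- list(
  BN1  = list(dag = "A>B;A>C;B>C;A>D;B>D;C>D", notation = "ABCD",
              terms = "p(B|A)p(A)p(C|AB)p(D|ABC)", ind = character()),
  BN2  = list(dag = "C>A;D>A;C>B;D>B;C>D", notation = "ACD:BCD",
              terms = "p(A|CD)p(C)p(B|CD)p(D|C)",
              ind = "(A ⊥ B | C, D)"),
  BN3  = list(dag = "A>C;B>C;A>D;B>D;C>D", notation = "ABCD_A:B_",
              terms = "p(C|AB)p(A)p(B)p(D|ABC)", ind = "(A ⊥ B)"),
  BN4  = list(dag = "C>A;C>B;A>D;B>D;C>D", notation = "ABCD_AC:BC_",
              terms = "p(A|C)p(C)p(B|C)p(D|ABC)", ind = "(A ⊥ B | C)"),
  BN5  = list(dag = "D>A;C>B;D>B;D>C", notation = "BCD:AD",
              terms = "p(A|D)p(D)p(B|CD)p(C|D)",
              ind = "(A ⊥ B, C | D)"),
  BN6  = list(dag = "C>B;A>D;B>D;C>D", notation = "ABCD_BC:A_",
              terms = "p(B|C)p(C)p(D|ABC)p(A)", ind = "(A ⊥ B, C)"),
  BN7  = list(dag = "B>C;D>C;A>D;B>D", notation = "BCD:ABD_A:B_",
              terms = "p(C|BD)p(B)p(D|AB)p(A)",
              ind = c("(A ⊥ B)", "(A ⊥ C | B, D)")),
  BN8  = list(dag = "C>A;D>A;C>B;D>B", notation = "ACD_C:D_:BCD_C:D_",
              terms = "p(A|CD)p(C)p(D)p(B|CD)",
              ind = c("(C ⊥ D)", "(A ⊥ B | C, D)")),
  BN9  = list(dag = "C>A;C>B;A>D;B>D", notation = "ABD:ABC_AC:BC_",
              terms = "p(A|C)p(C)p(B|C)p(D|AB)",
              ind = c("(A ⊥ B | C)", "(C ⊥ D | A, B)")),
  BN10 = list(dag = "C>B;B>D;C>D;A", notation = "BCD:A",
              terms = "p(A)p(B|C)p(C)p(D|BC)",
              ind = "(A ⊥ B, C, D)"),
  BN11 = list(dag = "D>A;D>B;D>C", notation = "AD:BD:CD",
              terms = "p(A|D)p(D)p(B|D)p(C|D)",
              ind = c("(A ⊥ B, C | D)", "(B ⊥ C | D)")),
  BN12 = list(dag = "A>D;B>D;C>D", notation = "ABCD_A:B:C_",
              terms = "p(D|ABC)p(A)p(B)p(C)",
              ind = c("(A ⊥ B, C)", "(B ⊥ C)")),
  BN13 = list(dag = "A>D;C>D;D>B", notation = "ACD_A:C_:BD",
              terms = "p(B|D)p(D|AC)p(A)p(C)",
              ind = c("(A ⊥ C)", "(B ⊥ A, C | D)")),
  BN14 = list(dag = "D>A;D>B;B>C", notation = "AD:BC:BD",
              terms = "p(A|D)p(D)p(B|D)p(C|B)",
              ind = c("(A ⊥ B | D)", "(C ⊥ A, D | B)"),
              ind_alt = c("(C ⊥ D | B)", "(A ⊥ B, C | D)")),
  BN15 = list(dag = "B>C;A>D;B>D", notation = "ABD_A:B_:BC",
              terms = "p(C|B)p(B)p(D|AB)p(A)",
              ind = c("(A ⊥ B, C)", "(C ⊥ D | A, B)")),
  BN16 = list(dag = "D>B;D>C;A", notation = "BD:CD:A",
              terms = "p(B|D)p(D)p(C|D)p(A)",
              ind = c("(B ⊥ C | D)", "(A ⊥ B, C, D)")),
  BN17 = list(dag = "B>D;C>D;A", notation = "BCD_B:C_:A",
              terms = "p(D|BC)p(B)p(C)p(A)",
              ind = c("(B ⊥ C)", "(A ⊥ B, C, D)")),
  BN18 = list(dag = "B>C;A>D", notation = "AD:BC",
              terms = "p(C|B)p(B)p(D|A)p(A)",
              ind = "(A, D ⊥ B, C)"),
  BN19 = list(dag = "C>D;A;B", notation = "CD:A:B",
              terms = "p(D|C)p(C)p(A)p(B)",
              ind = c("(B ⊥ C, D)", "(A ⊥ B, C, D)")),
  BN20 = list(dag = "A;B;C;D", notation = "A:B:C:D",
              terms = "p(A)p(B)p(C)p(D)",
              ind = c("(A ⊥ B, C, D)", "(B ⊥ C, D)", "(C ⊥ D)"))
)

# Table of equivalent Rho / RA / BN general graphs: specific example and
# independencies (labels per the published convention).
equivalent_pair_rows <- list(
  rho1  = list(example = "ABCD", ind = character()),
  rho2  = list(example = "ACD:BCD", ind = "(A ⊥ B | C, D)"),
  rho3  = list(example = "BCD:AD", ind = "(A ⊥ B, C | D)"),
  rho5  = list(example = "BCD:A", ind = "(A ⊥ B, C, D)"),
  rho6  = list(example = "AD:BD:CD",
               ind = c("(A ⊥ B, C | D)", "(B ⊥ C | D)")),
  rho7  = list(example = "AD:BC:BD",
               ind = c("(A ⊥ B | D)", "(C ⊥ A, D | B)"),
               ind_alt = c("(C ⊥ D | B)", "(A ⊥ B, C | D)")),
  rho8  = list(example = "BD:CD:A",
               ind = c("(B ⊥ C | D)", "(A ⊥ B, C, D)")),
  rho9  = list(example = "AD:BC", ind = "(A, D ⊥ B, C)"),
  rho10 = list(example = "CD:A:B",
               ind = c("(B ⊥ C, D)", "(A ⊥ B, C, D)")),
  rho11 = list(example = "A:B:C:D",
               ind = c("(A ⊥ B, C, D)", "(B ⊥ C, D)", "(C ⊥ D)"))
)

# Directed-lattice expectations: retained BN general -> RA equivalent
# (specific examples with DV Z), per the published mapping.
ra_equivalent_rows <- list(
  BN7  = list(bn = "ABZ_A:B_:BCZ", ra = "ABZ:BCZ"),
  BN11 = list(bn = "AZ:BZ:CZ",     ra = "AZ:BZ:CZ"),
  BN12 = list(bn = "ABCZ_A:B:C_",  ra = "ABCZ"),
  BN13 = list(bn = "ACZ_A:C_:BZ",  ra = "ACZ:BZ"),
  BN16 = list(bn = "BZ:CZ:A",      ra = "BZ:CZ:A"),
  BN17 = list(bn = "BCZ_B:C_:A",   ra = "ABC:BCZ"),
  BN19 = list(bn = "CZ:A:B",       ra = "ABC:CZ"),
  BN20 = list(bn = "A:B:C:Z",      ra = "ABC:Z")
)

# multiset of p(child|parents) terms from a factorization string
term_multiset <- function(txt) {
  sort(regmatches(txt, gregexpr("p\\([^)]*\\)", txt))[[1]])
}

# normalize a factorization term so parent order does not matter
norm_terms <- function(txt) {
  sort(vapply(term_multiset(txt), function(t) {
    inner <- sub("^p\\(", "", sub("\\)$", "", t))
    parts <- strsplit(inner, "|", fixed = TRUE)[[1]]
    if (length(parts) == 2L)
      paste0("p(", parts[1L], "|",
             paste(sort(strsplit(parts[2L], "")[[1]]), collapse = ""), ")")
    else t
  }, "", USE.NAMES = FALSE))
}

display_set <- function(ind_set) sort(vapply(ind_set$display, format, ""))

# cache for expensive n = 4 enumerations, shared across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}
abcd4 <- function() cached("sys4", abcd_system())
specific4 <- function() cached("sp4", specific_classes(abcd4()))
ra4 <- function() cached("ra4", ra_lattice(abcd4()))
joint4 <- function() cached("joint4", build_joint(abcd4()))
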