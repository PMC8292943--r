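#' Configuration for the synthetic-corpus generator
#'
#' The generator emulates the two inputs the pipeline consumes — a MeSH
#' vocabulary and a corpus of indexed publications — with a controllable
#' H/I/T mixture so every downstream stage is testable offline with known
#' ground truth.
#'
#' Defaults reflect the study conditions the method was built for: articles
#' carry about six major topics (MEDLINE articles usually carry 5-10 MeSH
#' primary terms) drawn per-code from an H/I/T mixture of
#' (0.45, 0.27, 0.28) — the composition observed for a large
#' health-informatics corpus — over a vocabulary whose branch sizes keep
#' every sampling pool comfortably larger than any single article's topic
#' list.
#'
#' @param n_articles Number of articles to generate.
#' @param mixture Named probabilities `c(h=, i=, t=)` summing to 1: the
#'   chance that each drawn topic code falls in H, I or T.
#' @param topics_mean Mean number of category topics per article (min 1;
#'   counts are 1 + Poisson(topics_mean - 1)).
#' @param seed Integer seed; one seeded stream drives the whole run.
#' @param included_only Resample each article until it carries both an H
#'   and an I topic (the corpus-inclusion rule); biases the realised
#'   mixture towards H and I, so parameter-recovery checks use the default
#'   `FALSE`.
#' @param p_distractor Probability an article also gets one uncategorised
#'   (distractor-branch) major topic.
#' @param vocabulary Named integer vector of leaf-descriptor counts per
#'   sampling branch: `diseases` (C), `health` (N01.400), `public_health`
#'   (N06.850), `ph_discipline` (H02.403.720), `info_science` (L),
#'   `techniques` (E), `distractor` (B/D).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_articles = 1000,
                       mixture = c(h = 0.45, i = 0.27, t = 0.28),
                       topics_mean = 6, seed = 1L, included_only = FALSE,
                       p_distractor = 0.15,
                       vocabulary = c(diseases = 60L, health = 12L,
                                      public_health = 12L, ph_discipline = 6L,
                                      info_science = 30L, techniques = 40L,
                                      distractor = 12L)) {
  stopifnot(n_articles >= 1, topics_mean >= 1)
  if (abs(sum(mixture) - 1) > 1e-9 || any(mixture < 0)) {
    abort("mixture must be non-negative probabilities summing to 1")
  }
  if (is.null(names(mixture))) names(mixture) <- c("h", "i", "t")
  required <- c("diseases", "health", "public_health", "ph_discipline",
                "info_science", "techniques", "distractor")
  if (any(!required %in% names(vocabulary)) ||
      any(vocabulary[required] < 1)) {
    abort("vocabulary must request at least one descriptor per branch")
  }
  structure(list(n_articles = as.integer(n_articles), mixture = mixture,
                 topics_mean = topics_mean, seed = as.integer(seed),
                 included_only = isTRUE(included_only),
                 p_distractor = p_distractor, vocabulary = vocabulary),
            class = "sim_config")
}

# fixed skeleton: internal nodes and named subtree-test chains. Tree
# numbers printed in the published H-I-T category and ICD correspondence
# tables are kept verbatim; everything else is a synthetic stand-in.
fixture_skeleton <- function() {
  tribble_rows <- list(
    c("D002318", "Cardiovascular Diseases", "C14"),
    c("D014652", "Vascular Diseases", "C14.907"),
    c("D006973", "Hypertension", "C14.907.489"),
    c("D046110", "Hypertension, Pregnancy-Induced",
      "C13.703.395|C14.907.489.480"),
    c("D005261", "Female Urogenital Diseases and Pregnancy Complications",
      "C13"),
    c("D011248", "Pregnancy Complications", "C13.703"),
    c("D006331", "Heart Diseases", "C14.280"),
    c("D017202", "Myocardial Ischemia", "C14.280.647|C14.907.585"),
    c("D009203", "Myocardial Infarction", "C14.280.647.500|C14.907.585.500"),
    c("D007154", "Immune System Diseases", "C20"),
    c("D052776", "Urogenital Diseases", "C12"),
    c("D007674", "Kidney Diseases", "C12.777.419"),
    c("D003928", "Diabetic Nephropathies", "C12.777.419.192"),
    c("D009369", "Neoplasms", "C04"),
    c("D007239", "Infections", "C01"),
    c("D011154", "Population Characteristics", "N01"),
    c("D006262", "Health", "N01.400"),
    c("D004778", "Environment and Public Health", "N06"),
    c("D011634", "Public Health", "N06.850|H02.403.720"),
    c("D006281", "Health Occupations", "H02"),
    c("D008511", "Medicine", "H02.403"),
    c("D004813", "Epidemiology", "H02.403.720.500"),
    c("D007254", "Information Science", "L01"),
    c("D009622", "Computing Methodologies", "L01.224"),
    c("D000465", "Algorithms", "L01.224.050"),
    c("D001185", "Artificial Intelligence", "L01.224.050.375"),
    c("D000069550", "Machine Learning", "L01.224.050.375.530"),
    c("D009323", "Natural Language Processing", "L01.224.050.375.580"),
    c("D016571", "Neural Networks, Computer", "L01.224.050.375.605"),
    c("D003142", "Communications Media", "L01.178"),
    c("D063990", "Informatics", "L01.453"),
    c("D008490", "Medical Informatics", "L01.453.245"),
    c("D017216", "Telemedicine", "L01.453.245.945|L01.224.134"),
    c("D057286", "Electronic Health Records", "L01.453.245.300"),
    c("D003933", "Diagnosis", "E01"),
    c("D013812", "Therapeutics", "E02"),
    c("D008919", "Investigative Techniques", "E05"),
    c("D004864", "Equipment and Supplies", "E07"),
    c("D001829", "Organisms Distractor Branch", "B01"),
    c("D009930", "Chemicals Distractor Branch", "D02"),
    c("D000poly", "Unclassifiable Publication Type", NA)
  )
  bind_rows(purrr::map(tribble_rows, function(r) {
    tn <- if (is.na(r[3])) NA_character_ else
      strsplit(r[3], "|", fixed = TRUE)[[1]]
    tibble(ui = r[1], name = r[2], tree_number = tn)
  }))
}

# evenly spread k leaves under the given parent codes
fixture_leaves <- function(parents, k, stem) {
  parent <- parents[(seq_len(k) - 1) %% length(parents) + 1]
  idx <- seq_len(k)
  tibble(ui = sprintf("S%s%04d", stem, idx),
         name = sprintf("Synthetic %s Term %03d", stem, idx),
         tree_number = sprintf("%s.%03d", parent, 100 + idx))
}

#' Build a synthetic fixture vocabulary
#'
#' Deterministic for a given configuration (the RNG is not consulted): a
#' fixed skeleton of named internal nodes — including parent/child chains
#' for subtree tests, a descriptor with two tree numbers in one category,
#' and distractor branches — plus the configured number of single-code
#' leaf descriptors per branch, which form the generator's sampling pools.
#'
#' @param config A [sim_config()].
#' @return A [mesh_tree] with `mesh_year = "synthetic"`.
#' @export
make_fixture_tree <- function(config = sim_config()) {
  v <- config$vocabulary
  leaves <- bind_rows(
    fixture_leaves(c("C01", "C04", "C12.777.419", "C14.280", "C14.907"),
                   v[["diseases"]], "H"),
    fixture_leaves("N01.400", v[["health"]], "N"),
    fixture_leaves("N06.850", v[["public_health"]], "P"),
    fixture_leaves("H02.403.720", v[["ph_discipline"]], "Q"),
    fixture_leaves(c("L01.224", "L01.178", "L01.453"),
                   v[["info_science"]], "I"),
    fixture_leaves(c("E01", "E02", "E05", "E07"), v[["techniques"]], "T"),
    fixture_leaves(c("B01", "D02"), v[["distractor"]], "X"))
  mesh_tree(bind_rows(fixture_skeleton(), leaves), year = "synthetic")
}

# sampling pools: the generated leaves, keyed by category of their code
generator_pools <- function(tree, scheme = hit_scheme()) {
  leaves <- tree[grepl("^S[A-Z]\\d{4}$", tree$ui), , drop = FALSE]
  cat_lab <- classify_code(leaves$tree_number, scheme)
  list(H = leaves$name[!is.na(cat_lab) & cat_lab == "H"],
       I = leaves$name[!is.na(cat_lab) & cat_lab == "I"],
       T = leaves$name[!is.na(cat_lab) & cat_lab == "T"],
       none = leaves$name[is.na(cat_lab)])
}

#' Generate a synthetic corpus with known H-I-T composition
#'
#' Each article draws its number of category topics from
#' 1 + Poisson(topics_mean - 1), assigns each topic's category i.i.d. from
#' the mixture, and samples distinct leaf descriptors (one tree-number
#' code each) from the matching pools, so the ground-truth per-article
#' counts equal exactly what [hit_counts()] recovers from the records.
#' Distractor topics and a non-major heading exercise the classification
#' and major-topic filters without touching the truth.
#'
#' @param config A [sim_config()].
#' @param tree A fixture tree from [make_fixture_tree()] (built from
#'   `config` when omitted).
#' @return A list of class `hit_simulation`: `records` (a corpus tibble),
#'   `truth` (tibble `pmid`, `n_h`, `n_i`, `n_t`) and `config`.
#' @export
generate_corpus <- function(config = sim_config(), tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- make_fixture_tree(config)
  pools <- generator_pools(tree)
  mix <- config$mixture
  if (config$included_only && (mix[["h"]] <= 0 || mix[["i"]] <= 0)) {
    abort("included_only corpus is infeasible when the mixture gives H or I zero mass")
  }
  no_quals <- tibble(name = character(), major = logical())
  withr::with_seed(config$seed, {
    rows <- vector("list", config$n_articles)
    truth <- matrix(0L, nrow = config$n_articles, ncol = 3,
                    dimnames = list(NULL, c("H", "I", "T")))
    for (a in seq_len(config$n_articles)) {
      repeat {
        m <- 1L + rpois(1, config$topics_mean - 1)
        cats <- sample(c("H", "I", "T"), m, replace = TRUE, prob = mix)
        if (!config$included_only ||
            (any(cats == "H") && any(cats == "I"))) break
      }
      tab <- table(factor(cats, levels = c("H", "I", "T")))
      topics <- character(0)
      for (lab in c("H", "I", "T")) {
        k <- tab[[lab]]
        if (k == 0) next
        if (k > length(pools[[lab]])) {
          abort(paste0("sampling pool for ", lab, " too small (", k,
                       " draws requested): enlarge the vocabulary config"))
        }
        topics <- c(topics, sample(pools[[lab]], k))
      }
      truth[a, ] <- as.integer(tab)
      if (runif(1) < config$p_distractor) {
        topics <- c(topics, sample(pools$none, 1))
      }
      nm <- c(sample(topics), "Organisms Distractor Branch")
      headings <- tibble(
        descriptor_name = nm, descriptor_ui = NA_character_,
        major = c(rep(TRUE, length(nm) - 1), FALSE),
        qualifiers = rep(list(no_quals), length(nm)))
      rows[[a]] <- tibble(
        pmid = sprintf("SIM%06d", a),
        title = sprintf("Synthetic informatics article %d", a),
        year = sample(2010:2020, 1), language = "eng",
        country = sample(c("China", "United States"), 1),
        publication_types = list("Journal Article"),
        headings = list(headings))
    }
    records <- bind_rows(rows)
    structure(list(records = validate_corpus(records),
                   truth = tibble(pmid = records$pmid,
                                  n_h = truth[, "H"], n_i = truth[, "I"],
                                  n_t = truth[, "T"]),
                   config = config),
              class = "hit_simulation")
  })
}

#' @export
print.hit_simulation <- function(x, ...) {
  cat("<hit_simulation> ", nrow(x$records), " articles, mixture (",
      paste(format(x$config$mixture, digits = 3), collapse = ", "),
      "), seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
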