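# Literature triage: identify likely CvT-bearing publications from abstracts
# and MeSH annotations. Two routes: a MeSH term-enrichment rule (sqrt-of-
# class-size threshold) and a TF-IDF consensus classifier ensemble evaluated
# by 10-fold cross-validation with a 90% accuracy retention filter.

#' Stop-word list used by abstract preprocessing
#'
#' A standard English stop-word list shipped as editable plain text.
#'
#' @return Character vector of stop words.
#' @export
cvt_stop_words <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "cvtkit"),
            encoding = "UTF-8")
}

tokenize_text <- function(text) {
  regmatches(tolower(text), gregexpr("[a-z]+", tolower(text)))
}

split_mesh <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

# Count occurrences of a fixed vocabulary in each document.
count_matrix <- function(token_lists, vocabulary) {
  m <- matrix(0, nrow = length(token_lists), ncol = length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_along(token_lists)) {
    tb <- table(token_lists[[i]][token_lists[[i]] %in% vocabulary])
    if (length(tb)) m[i, names(tb)] <- as.numeric(tb)
  }
  m
}

#' Preprocess an abstract corpus into a document-term count table
#'
#' Lower-cases and tokenizes abstracts, removes stop words, then removes
#' tokens whose corpus-wide count falls strictly below the 25th percentile
#' (linear-interpolation quantile) of the distinct-token count distribution,
#' so uniform-count corpora lose nothing. Deterministic.
#'
#' @param corpus data frame with columns `doc_id` and `abstract` (and
#'   optionally `label`, `mesh_terms`).
#' @param stop_words words removed before counting.
#' @return List of class `cvt_token_table`: `doc_ids`, `vocabulary`, `counts`
#'   (documents x terms count matrix), `removed_low_frequency`.
#' @export
preprocess_abstracts <- function(corpus, stop_words = cvt_stop_words()) {
  stopifnot(nrow(corpus) > 0, all(nzchar(corpus$abstract)))
  toks <- tokenize_text(corpus$abstract)
  toks <- lapply(toks, function(tk) tk[!tk %in% stop_words])
  total <- table(unlist(toks))
  if (length(total) == 0)
    cvt_error("cvt_degenerate_corpus_error",
              "no tokens remain after stop-word removal")
  q25 <- unname(quantile(as.numeric(total), 0.25, type = 7))
  keep <- names(total)[as.numeric(total) >= q25]
  if (length(keep) == 0)
    cvt_error("cvt_degenerate_corpus_error",
              "vocabulary is empty after low-frequency filtering")
  structure(list(doc_ids = corpus$doc_id, vocabulary = sort(keep),
                 counts = count_matrix(toks, sort(keep)),
                 removed_low_frequency = sort(setdiff(names(total), keep))),
            class = "cvt_token_table")
}

#' TF-IDF document-term weight matrix
#'
#' Weights are raw term count x smoothed inverse document frequency
#' `ln((1 + N) / (1 + df)) + 1`, with each document row normalized to unit
#' Euclidean length. A term present in every document receives only the
#' smoothing floor.
#'
#' @param token_table a [preprocess_abstracts()] result.
#' @return Documents x terms matrix (rownames = doc ids) with attribute
#'   `idf` (named vector, reusable to featurize new documents).
#' @export
tfidf_features <- function(token_table) {
  stopifnot(inherits(token_table, "cvt_token_table"))
  counts <- token_table$counts
  if (nrow(counts) < 2)
    cvt_error("cvt_input_error", "TF-IDF needs >= 2 documents")
  N <- nrow(counts)
  df <- colSums(counts > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  w <- sweep(counts, 2, idf, `*`)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w <- w / nrm
  rownames(w) <- token_table$doc_ids
  attr(w, "idf") <- idf
  w
}

apply_tfidf <- function(abstracts, vocabulary, idf,
                        stop_words = cvt_stop_words()) {
  toks <- tokenize_text(abstracts)
  toks <- lapply(toks, function(tk) tk[!tk %in% stop_words])
  counts <- count_matrix(toks, vocabulary)
  w <- sweep(counts, 2, idf, `*`)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w / nrm
}

#' Extract class-enriched MeSH feature sets
#'
#' For each class, the features are the MeSH terms whose document count in
#' that class is strictly greater than the square root of the class size.
#' Terms qualifying in both classes are removed from both sets.
#'
#' @param corpus labelled data frame with columns `label`
#'   (positive/negative) and `mesh_terms` (pipe-separated).
#' @return List of class `mesh_feature_sets`: `positive_features`,
#'   `negative_features`, `thresholds`.
#' @export
mesh_feature_extraction <- function(corpus) {
  stopifnot(all(corpus$label %in% c("positive", "negative")))
  feats <- list()
  thresholds <- c()
  for (cl in c("positive", "negative")) {
    sub <- corpus[corpus$label == cl, , drop = FALSE]
    if (nrow(sub) == 0)
      cvt_error("cvt_input_error", sprintf("class '%s' is empty", cl))
    terms <- lapply(sub$mesh_terms, split_mesh)
    counts <- table(unlist(lapply(terms, unique)))
    thr <- sqrt(nrow(sub))
    thresholds[cl] <- thr
    feats[[cl]] <- names(counts)[as.numeric(counts) > thr]
    if (length(feats[[cl]]) == 0)
      cvt_warning("cvt_empty_features_warning",
                  sprintf("no enriched MeSH features for class '%s'", cl))
  }
  overlap <- intersect(feats$positive, feats$negative)
  structure(list(positive_features = sort(setdiff(feats$positive, overlap)),
                 negative_features = sort(setdiff(feats$negative, overlap)),
                 thresholds = thresholds),
            class = "mesh_feature_sets")
}

#' Classify publications by the MeSH enrichment rule
#'
#' A record is positive iff it carries at least one positive MeSH feature and
#' zero negative MeSH features; otherwise negative.
#'
#' @param records a character vector of MeSH terms (one record), or a data
#'   frame with a `mesh_terms` pipe-separated column (many records).
#' @param feature_sets a [mesh_feature_extraction()] result.
#' @return `"positive"`/`"negative"` (vector for a data frame input).
#' @export
mesh_rule_classify <- function(records, feature_sets) {
  stopifnot(inherits(feature_sets, "mesh_feature_sets"))
  one <- function(terms) {
    if (any(terms %in% feature_sets$positive_features) &&
        !any(terms %in% feature_sets$negative_features)) "positive"
    else "negative"
  }
  if (is.data.frame(records))
    vapply(records$mesh_terms, function(x) one(split_mesh(x)), character(1),
           USE.NAMES = FALSE)
  else one(records)
}

#' Ensemble specification
#'
#' @param members classifier family identifiers; see
#'   [ensemble_member_families()].
#' @param cv_folds number of cross-validation folds (default 10).
#' @param accuracy_inclusion_threshold minimum CV accuracy for a member to be
#'   retained in the consensus (default 0.90).
#' @param consensus_fraction vote fraction required to call a record positive
#'   (1.0 = unanimity, 0.75 = 75% of members).
#' @param undersample_negatives undersample the negative class to the
#'   positive-class size before training (default TRUE).
#' @param random_seed seed controlling undersampling, fold assignment and any
#'   stochastic member.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(members = names(ensemble_member_families()),
                          cv_folds = 10,
                          accuracy_inclusion_threshold = 0.90,
                          consensus_fraction = 1.0,
                          undersample_negatives = TRUE, random_seed = 1) {
  stopifnot(cv_folds >= 2, consensus_fraction > 0, consensus_fraction <= 1)
  stopifnot(all(members %in% names(ensemble_member_families())))
  structure(list(members = members, cv_folds = cv_folds,
                 accuracy_inclusion_threshold = accuracy_inclusion_threshold,
                 consensus_fraction = consensus_fraction,
                 undersample_negatives = undersample_negatives,
                 random_seed = random_seed),
            class = "ensemble_spec")
}

#' Available classifier families for the consensus ensemble
#'
#' Seven families spanning the common text-classification toolbox: Gaussian
#' naive Bayes, ridge-penalized logistic regression, linear support vector
#' machine, k-nearest neighbours (k = 3 and 5), a decision tree and a random
#' forest. Each entry provides `fit(x, y)` and `predict(model, x)` on TF-IDF
#' feature matrices.
#'
#' @return Named list of family definitions.
#' @export
ensemble_member_families <- function() {
  as_df <- function(x) {
    d <- as.data.frame(x)
    colnames(d) <- paste0("f", seq_len(ncol(x)))
    d
  }
  list(
    naive_bayes = list(
      fit = function(x, y) e1071::naiveBayes(as_df(x), y),
      predict = function(m, x) as.character(predict(m, as_df(x)))),
    logistic_ridge = list(
      fit = function(x, y) glmnet::glmnet(x, y, family = "binomial",
                                          alpha = 0, lambda = 0.01),
      predict = function(m, x)
        as.character(predict(m, x, type = "class")[, 1])),
    svm_linear = list(
      fit = function(x, y) e1071::svm(x, y, kernel = "linear",
                                      scale = FALSE),
      predict = function(m, x) as.character(predict(m, x))),
    knn3 = list(
      fit = function(x, y) list(x = x, y = y, k = 3),
      predict = function(m, x)
        as.character(class::knn(m$x, x, m$y, k = m$k))),
    knn5 = list(
      fit = function(x, y) list(x = x, y = y, k = 5),
      predict = function(m, x)
        as.character(class::knn(m$x, x, m$y, k = m$k))),
    decision_tree = list(
      fit = function(x, y) {
        d <- as_df(x); d$.y <- y
        rpart::rpart(.y ~ ., data = d, method = "class",
                     control = rpart::rpart.control(minsplit = 4,
                                                    cp = 0.01))
      },
      predict = function(m, x)
        as.character(predict(m, as_df(x), type = "class"))),
    random_forest = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 200),
      predict = function(m, x) as.character(predict(m, x)))
  )
}

#' Train the consensus classifier ensemble
#'
#' Undersamples the negative class to the positive-class size (seeded),
#' builds TF-IDF features on the balanced corpus, evaluates every member
#' family by stratified k-fold cross-validation, retains the members whose CV
#' accuracy reaches the inclusion threshold, and refits the retained members
#' on the full balanced corpus. Deterministic given the spec seed.
#'
#' @param corpus labelled data frame (`doc_id`, `label`, `abstract`, and
#'   optionally `mesh_terms`).
#' @param spec an [ensemble_spec()].
#' @return Object of class `cvt_ensemble`: fitted `members`,
#'   `cv_accuracies` (all families), `retained`, plus the vocabulary and IDF
#'   needed to featurize new documents.
#' @export
train_consensus_ensemble <- function(corpus, spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"),
            all(corpus$label %in% c("positive", "negative")))
  n_pos <- sum(corpus$label == "positive")
  n_neg <- sum(corpus$label == "negative")
  if (min(n_pos, n_neg) < spec$cv_folds)
    cvt_error("cvt_input_error",
              "each class must have at least as many documents as CV folds")
  families <- ensemble_member_families()[spec$members]

  with_private_seed(spec$random_seed, {
    balanced <- corpus
    if (spec$undersample_negatives && n_neg > n_pos) {
      neg_idx <- which(corpus$label == "negative")
      keep_neg <- sort(sample(neg_idx, n_pos))
      balanced <- corpus[sort(c(which(corpus$label == "positive"),
                                keep_neg)), , drop = FALSE]
    }
    prep <- preprocess_abstracts(balanced)
    x <- tfidf_features(prep)
    y <- factor(balanced$label, levels = c("negative", "positive"))

    folds <- integer(nrow(balanced))
    for (cl in levels(y)) {
      ix <- which(y == cl)
      folds[ix] <- sample(rep(seq_len(spec$cv_folds),
                              length.out = length(ix)))
    }

    cv_acc <- setNames(numeric(length(families)), names(families))
    for (j in seq_along(families)) {
      fam <- families[[j]]
      pred <- character(nrow(balanced))
      for (f in seq_len(spec$cv_folds)) {
        tr <- folds != f
        set.seed(spec$random_seed * 1000L + j * 100L + f)
        m <- fam$fit(x[tr, , drop = FALSE], y[tr])
        pred[!tr] <- fam$predict(m, x[!tr, , drop = FALSE])
      }
      cv_acc[j] <- mean(pred == as.character(y))
    }

    retained <- names(cv_acc)[cv_acc >= spec$accuracy_inclusion_threshold]
    if (length(retained) == 0)
      cvt_error("cvt_empty_ensemble_error",
                paste("no member reached the CV accuracy inclusion",
                      "threshold; consider lowering",
                      "accuracy_inclusion_threshold"))
    members <- list()
    for (nm in retained) {
      set.seed(spec$random_seed * 1000L + match(nm, names(families)))
      members[[nm]] <- families[[nm]]$fit(x, y)
    }
    structure(list(members = members, cv_accuracies = cv_acc,
                   retained = retained, vocabulary = prep$vocabulary,
                   idf = attr(x, "idf"), spec = spec,
                   n_training = nrow(balanced)),
              class = "cvt_ensemble")
  })
}

#' @export
print.cvt_ensemble <- function(x, ...) {
  cat(sprintf("<cvt_ensemble> %d/%d members retained (threshold %.2f)\n",
              length(x$retained), length(x$cv_accuracies),
              x$spec$accuracy_inclusion_threshold))
  for (nm in names(x$cv_accuracies))
    cat(sprintf("  %-15s CV accuracy %.3f%s\n", nm, x$cv_accuracies[nm],
                if (nm %in% x$retained) "  [retained]" else ""))
  invisible(x)
}

#' Consensus classification of abstracts
#'
#' Each retained member votes; a record is positive iff the fraction of
#' positive votes is at least `consensus_fraction` (1.0 = all members must
#' agree, the stricter rule; 0.75 = three quarters of the members).
#'
#' @param ensemble a [train_consensus_ensemble()] result.
#' @param records data frame with an `abstract` column (plus `doc_id`).
#' @param consensus_fraction vote fraction required for a positive call;
#'   defaults to the ensemble spec's value.
#' @return Character vector of `"positive"`/`"negative"`.
#' @export
consensus_classify <- function(ensemble, records,
                               consensus_fraction = NULL) {
  stopifnot(inherits(ensemble, "cvt_ensemble"))
  if (length(ensemble$members) == 0)
    cvt_error("cvt_empty_ensemble_error", "ensemble has no members")
  if (is.null(consensus_fraction))
    consensus_fraction <- ensemble$spec$consensus_fraction
  stopifnot(consensus_fraction > 0, consensus_fraction <= 1)
  x <- apply_tfidf(records$abstract, ensemble$vocabulary, ensemble$idf)
  votes <- matrix(0, nrow = nrow(x), ncol = length(ensemble$members))
  with_private_seed(ensemble$spec$random_seed + 7919L, {
    for (j in seq_along(ensemble$members)) {
      nm <- names(ensemble$members)[j]
      fam <- ensemble_member_families()[[nm]]
      votes[, j] <- fam$predict(ensemble$members[[nm]], x) == "positive"
    }
  })
  ifelse(rowMeans(votes) >= consensus_fraction - 1e-12, "positive",
         "negative")
}
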