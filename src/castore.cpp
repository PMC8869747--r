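#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Pair-coding dictionary parse (CASToRe family).
//
// The dictionary starts with only the empty word (index 0). At each step the
// new word is prefix.suffix, where prefix is the longest dictionary word
// (possibly empty) matching the unread input and suffix is the longest
// dictionary word matching what follows the prefix, falling back to the
// single next raw symbol when no non-empty word matches. A final incomplete
// word is emitted with an empty suffix. Words are stored in a trie holding
// exactly the defined words: the dictionary is not prefix-closed, so
// "longest match" means longest *defined* word.

namespace {

struct Trie {
  std::vector<std::unordered_map<int, int> > child;
  std::vector<int> word_id; // -1 = interior node; root carries the empty word 0
  Trie() {
    child.emplace_back();
    word_id.push_back(0);
  }
  // longest dictionary word matching s[p..]; nonempty_only excludes the empty word
  std::pair<int, int> longest(const std::vector<int>& s, size_t p,
                              bool nonempty_only) const {
    int node = 0, best_id = nonempty_only ? -1 : 0, best_len = 0, len = 0;
    while (p + len < s.size()) {
      std::unordered_map<int, int>::const_iterator it =
          child[node].find(s[p + len]);
      if (it == child[node].end()) break;
      node = it->second;
      ++len;
      if (word_id[node] >= 0) {
        best_id = word_id[node];
        best_len = len;
      }
    }
    return std::make_pair(best_id, best_len);
  }
  void insert(const std::vector<int>& s, size_t p, int len, int id) {
    int node = 0;
    for (int k = 0; k < len; ++k) {
      std::unordered_map<int, int>::iterator it = child[node].find(s[p + k]);
      if (it == child[node].end()) {
        child[node][s[p + k]] = (int)child.size();
        child.emplace_back();
        word_id.push_back(-1);
        node = (int)child.size() - 1;
      } else {
        node = it->second;
      }
    }
    word_id[node] = id;
  }
};

} // namespace

// Returns parallel event vectors: prefix index (0 = empty word), suffix type
// (0 = dictionary word, 1 = literal symbol, 2 = empty terminal), suffix value,
// and the length of the word each event defines.
// [[Rcpp::export(name = ".castore_parse_cpp")]]
List castore_parse_cpp(IntegerVector symbols, int alphabet_size) {
  const size_t n = symbols.size();
  if (n == 0) stop("empty symbol sequence");
  std::vector<int> s(n);
  for (size_t i = 0; i < n; ++i) {
    int v = symbols[i];
    if (v == NA_INTEGER || v < 1 || v > alphabet_size)
      stop("symbol at position %d is outside {1..%d}", (int)(i + 1),
           alphabet_size);
    s[i] = v;
  }
  Trie trie;
  std::vector<int> prefix, stype, sval, wlen;
  size_t p = 0;
  int next_id = 1;
  while (p < n) {
    std::pair<int, int> pre = trie.longest(s, p, false);
    size_t q = p + pre.second;
    int type, val, len = pre.second;
    if (q >= n) { // prefix consumed the tail: terminal event, empty suffix
      type = 2;
      val = NA_INTEGER;
    } else {
      std::pair<int, int> suf = trie.longest(s, q, true);
      if (suf.first >= 0) {
        type = 0;
        val = suf.first;
        len += suf.second;
      } else {
        type = 1;
        val = s[q];
        len += 1;
      }
    }
    trie.insert(s, p, len, next_id);
    prefix.push_back(pre.first);
    stype.push_back(type);
    sval.push_back(val);
    wlen.push_back(len);
    ++next_id;
    p += (size_t)len;
  }
  return List::create(_["prefix"] = wrap(prefix), _["suffix_type"] = wrap(stype),
                      _["suffix"] = wrap(sval), _["word_length"] = wrap(wlen));
}

// [[Rcpp::export(name = ".castore_decode_cpp")]]
IntegerVector castore_decode_cpp(IntegerVector prefix, IntegerVector stype,
                                 IntegerVector sval, int alphabet_size) {
  const int m = prefix.size();
  if (m == 0) stop("empty event list");
  std::vector<std::vector<int> > words(1); // word 0 = empty
  std::vector<int> out;
  for (int k = 0; k < m; ++k) {
    int pi = prefix[k];
    if (pi < 0 || pi >= (int)words.size())
      stop("event %d: prefix index %d refers to an undefined word", k + 1, pi);
    std::vector<int> w = words[pi];
    if (stype[k] == 0) {
      int si = sval[k];
      if (si < 1 || si >= (int)words.size())
        stop("event %d: suffix index %d refers to an undefined word", k + 1, si);
      w.insert(w.end(), words[si].begin(), words[si].end());
    } else if (stype[k] == 1) {
      int lit = sval[k];
      if (lit < 1 || lit > alphabet_size)
        stop("event %d: literal %d outside {1..%d}", k + 1, lit, alphabet_size);
      w.push_back(lit);
    } else if (stype[k] != 2) {
      stop("event %d: unknown suffix type %d", k + 1, (int)stype[k]);
    }
    if (w.empty()) stop("event %d defines an empty word", k + 1);
    out.insert(out.end(), w.begin(), w.end());
    words.push_back(w);
  }
  return wrap(out);
}
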