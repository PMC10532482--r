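#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified nearest-neighbour folding objective (maximized):
// pair rewards GC = 3, AU = 2, GU = 1; +1 for every stacked pair
// (both (i,j) and (i+1,j-1) paired); hairpin loops need >= min_loop
// unpaired bases; only canonical pairs; ambiguity codes unpairable.

static int pair_reward(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return -1; // not pairable
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  const int NEG = -1000000000;
  // M[i][j]: best score on s[i..j]; P[i][j]: best score with (i,j) paired
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  std::vector< std::vector<int> > P(n, std::vector<int>(n, NEG));

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int pr = pair_reward(seq[i], seq[j]);
      if (pr > 0) {
        int w = (j - 1 >= i + 1) ? M[i + 1][j - 1] : 0;
        if (j - 1 > i + 1 && P[i + 1][j - 1] > NEG)
          w = std::max(w, P[i + 1][j - 1] + 1);
        P[i][j] = pr + w;
      }
      // M recursion: pair (i,k) for some k, or leave i unpaired
      int best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (P[i][k] > NEG) {
          int cand = P[i][k] + ((k + 1 <= j) ? M[k + 1][j] : 0);
          if (cand > best) best = cand;
        }
      }
      M[i][j] = best;
    }
  }

  // deterministic traceback: prefer pairing (i,k) with smallest k over
  // leaving i unpaired; inside a pair prefer the stacked continuation
  std::string db(n, '.');
  std::vector< std::pair<int,int> > stack;
  std::vector< std::pair<int,int> > tasks; // (i, j) M-intervals
  std::vector< std::pair<int,int> > pstack; // (i, j) P-pairs to expand
  if (n > 0) tasks.push_back(std::make_pair(0, n - 1));
  while (!tasks.empty() || !pstack.empty()) {
    if (!pstack.empty()) {
      int i = pstack.back().first, j = pstack.back().second;
      pstack.pop_back();
      db[i] = '('; db[j] = ')';
      stack.push_back(std::make_pair(i, j));
      int pr = pair_reward(seq[i], seq[j]);
      int interior = (j - 1 >= i + 1) ? M[i + 1][j - 1] : 0;
      if (j - 1 > i + 1 && P[i + 1][j - 1] > NEG &&
          P[i][j] == pr + P[i + 1][j - 1] + 1) {
        pstack.push_back(std::make_pair(i + 1, j - 1));
      } else if (j - 1 >= i + 1 && P[i][j] == pr + interior) {
        tasks.push_back(std::make_pair(i + 1, j - 1));
      }
      continue;
    }
    int i = tasks.back().first, j = tasks.back().second;
    tasks.pop_back();
    if (i >= j) continue;
    bool done = false;
    for (int k = i + min_loop + 1; k <= j && !done; ++k) {
      if (P[i][k] > NEG) {
        int cand = P[i][k] + ((k + 1 <= j) ? M[k + 1][j] : 0);
        if (cand == M[i][j]) {
          pstack.push_back(std::make_pair(i, k));
          if (k + 1 <= j) tasks.push_back(std::make_pair(k + 1, j));
          done = true;
        }
      }
    }
    if (!done) tasks.push_back(std::make_pair(i + 1, j));
  }

  IntegerMatrix pairs(stack.size(), 2);
  for (size_t r = 0; r < stack.size(); ++r) {
    pairs(r, 0) = stack[r].first + 1;  // 1-based for R
    pairs(r, 1) = stack[r].second + 1;
  }
  return List::create(_["score"] = (n > 0 ? M[0][n - 1] : 0),
                      _["dotbracket"] = db,
                      _["pairs"] = pairs);
}
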