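#include <Rcpp.h>
using namespace Rcpp;

// Donor matching for predictive mean matching (type-1 matching).
//
// For each target prediction, find the `d` observed-row predictions closest
// in absolute distance and return the index (1-based, into yhat_obs) of one
// donor drawn uniformly from that pool.  Distance ties at the pool boundary
// are broken uniformly at random, so every donor with a tied distance has
// equal inclusion probability.  Uses R's RNG stream for reproducibility.
//
// [[Rcpp::export(name = ".match_donors")]]
IntegerVector match_donors(NumericVector yhat_obs, NumericVector yhat_target,
                           int d) {
  int n = yhat_obs.size();
  int nt = yhat_target.size();
  if (d < 1) stop("donor count must be >= 1");
  if (d > n) stop("donor count exceeds the number of observed cases");

  // sort observed predictions once; nearest-d sets are contiguous windows
  std::vector<std::pair<double, int> > ord(n);
  for (int i = 0; i < n; ++i) ord[i] = std::make_pair(yhat_obs[i], i);
  std::sort(ord.begin(), ord.end());

  IntegerVector out(nt);
  std::vector<int> pool(d);
  for (int t = 0; t < nt; ++t) {
    double y = yhat_target[t];
    // binary search for insertion point
    int lo = 0, hi = n;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (ord[mid].first < y) lo = mid + 1; else hi = mid;
    }
    // grow a window of size d by repeatedly taking the nearer end;
    // break exact distance ties with a fair coin
    int left = lo - 1, right = lo;
    for (int k = 0; k < d; ++k) {
      bool take_left;
      if (left < 0) take_left = false;
      else if (right >= n) take_left = true;
      else {
        double dl = y - ord[left].first;
        double dr = ord[right].first - y;
        if (dl < dr) take_left = true;
        else if (dr < dl) take_left = false;
        else take_left = (unif_rand() < 0.5);
      }
      pool[k] = take_left ? left-- : right++;
    }
    int pick = (int)(unif_rand() * d);
    if (pick == d) pick = d - 1;  // guard against unif_rand() == 1
    out[t] = ord[pool[pick]].second + 1;
  }
  return out;
}
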