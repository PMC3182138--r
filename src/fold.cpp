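// Minimum-free-energy RNA secondary structure by nearest-neighbor dynamic
// programming (Zuker-style): stacking energies, hairpin/bulge/internal loop
// penalties, affine multiloops. No pseudoknots; internal loops capped at
// MAXLOOP unpaired nucleotides total. Energies in dcal/mol (1/100 kcal/mol).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <cmath>
using namespace Rcpp;

static const int INF = 1000000;
static const int MAXLOOP = 12;   // max unpaired nt in a bulge/internal loop
static const int MINHP = 3;      // min hairpin loop size
static const int ML_CLOSE = 340; // multiloop closing penalty
static const int ML_BRANCH = 40; // per-branch penalty
static const int ML_UNPAIRED = 0;
static const int TERM_AU = 50;   // non-GC helix-end penalty
static const int ASYM = 60;      // internal loop asymmetry, per nt, capped
static const int ASYM_MAX = 300;

// pair types: 0 CG, 1 GC, 2 GU, 3 UG, 4 AU, 5 UA, -1 none
static int ptype(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

// Turner-style stacking energies, STACK_[pt(i,j)][pt(i+1,j-1)]
// row = outer pair, col = inner pair; order CG GC GU UG AU UA
static const int STACK_[6][6] = {
  { -240, -330, -210, -140, -210, -210 }, // CG
  { -330, -340, -250, -150, -220, -240 }, // GC
  { -210, -250,  130,  -50, -140, -130 }, // GU
  { -140, -150,  -50,   30,  -60, -100 }, // UG
  { -210, -220, -140,  -60, -110,  -90 }, // AU
  { -210, -240, -130, -100,  -90, -130 }  // UA
};

static const int HAIRPIN[31] = {
  INF, INF, INF, 540, 560, 570, 540, 600, 550, 640, 650, 660, 670, 678, 686,
  694, 701, 707, 713, 719, 725, 730, 735, 740, 744, 749, 753, 757, 761, 765, 769 };
static const int BULGE[31] = {
  INF, 380, 280, 320, 360, 400, 440, 459, 470, 480, 490, 500, 510, 519, 527,
  534, 541, 548, 554, 560, 565, 570, 575, 580, 585, 589, 594, 598, 602, 605, 609 };
static const int ILOOP[31] = {
  INF, INF, 150, 200, 250, 270, 290, 305, 318, 330, 340, 350, 358, 366, 373,
  380, 386, 392, 397, 402, 407, 412, 416, 420, 424, 428, 432, 435, 439, 442, 445 };

static int hairpinE(int size) {
  if (size < MINHP) return INF;
  if (size <= 30) return HAIRPIN[size];
  return HAIRPIN[30] + (int)(107.856 * std::log((double)size / 30.0));
}

static int termAU(int pt) { return pt >= 2 ? TERM_AU : 0; }

static int loopE(int n1, int n2, int pt1, int pt2) {
  int n = n1 + n2;
  if (n == 0) return STACK_[pt1][pt2];
  if (n1 == 0 || n2 == 0) { // bulge
    int e = (n <= 30) ? BULGE[n] : BULGE[30] + (int)(107.856 * std::log((double)n / 30.0));
    if (n > 1) e += termAU(pt1) + termAU(pt2); // helix interrupted
    return e;
  }
  int e = (n <= 30) ? ILOOP[n] : ILOOP[30] + (int)(107.856 * std::log((double)n / 30.0));
  int as = ASYM * std::abs(n1 - n2);
  e += (as > ASYM_MAX) ? ASYM_MAX : as;
  return e;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; i++) {
    char c = toupper(seq[i]);
    switch (c) {
      case 'A': s[i] = 0; break;
      case 'C': s[i] = 1; break;
      case 'G': s[i] = 2; break;
      case 'U': case 'T': s[i] = 3; break;
      default: stop("non-ACGTU character in sequence: '%c'", c);
    }
  }
  if (n < 2) {
    return List::create(_["structure"] = std::string(n, '.'),
                        _["energy"] = 0.0,
                        _["pairmate"] = IntegerVector(n, 0));
  }
  // V[i][j]: closed by pair (i,j); M[i][j]: >=1 multiloop branch
  std::vector<std::vector<int> > V(n, std::vector<int>(n, INF));
  std::vector<std::vector<int> > M(n, std::vector<int>(n, INF));
  std::vector<int> W(n + 1, 0); // W[j+1] = external energy of s[0..j]

  for (int d = MINHP + 1; d < n; d++) {
    for (int i = 0; i + d < n; i++) {
      int j = i + d;
      int pt = ptype(s[i], s[j]);
      if (pt >= 0) {
        int best = hairpinE(j - i - 1) + termAU(pt);
        // stack / bulge / internal
        int pmax = std::min(i + MAXLOOP + 1, j - 1 - MINHP);
        for (int p = i + 1; p <= pmax; p++) {
          int n1 = p - i - 1;
          int qmin = std::max(p + MINHP + 1, j - 1 - (MAXLOOP - n1));
          for (int q = j - 1; q >= qmin; q--) {
            if (V[p][q] >= INF) continue;
            int pt2 = ptype(s[p], s[q]);
            int e = loopE(n1, j - q - 1, pt, pt2) + V[p][q];
            if (e < best) best = e;
          }
        }
        // multiloop: closing pair + >=2 inner branches
        for (int k = i + 2; k < j - 1; k++) {
          if (M[i + 1][k] >= INF || M[k + 1][j - 1] >= INF) continue;
          int e = ML_CLOSE + ML_BRANCH + termAU(pt) + M[i + 1][k] + M[k + 1][j - 1];
          if (e < best) best = e;
        }
        V[i][j] = best;
      }
      // M
      int m = INF;
      if (M[i + 1][j] < m) m = M[i + 1][j] + ML_UNPAIRED;
      if (M[i][j - 1] + ML_UNPAIRED < m) m = M[i][j - 1] + ML_UNPAIRED;
      if (pt >= 0 && V[i][j] < INF) {
        int e = V[i][j] + ML_BRANCH + termAU(pt);
        if (e < m) m = e;
      }
      for (int k = i + 1; k < j; k++) {
        if (M[i][k] >= INF || M[k + 1][j] >= INF) continue;
        int e = M[i][k] + M[k + 1][j];
        if (e < m) m = e;
      }
      M[i][j] = m;
    }
  }
  for (int j = 0; j < n; j++) {
    int w = W[j]; // j unpaired
    for (int i = 0; i < j; i++) {
      int pt = ptype(s[i], s[j]);
      if (pt < 0 || V[i][j] >= INF) continue;
      int e = W[i] + V[i][j] + termAU(pt);
      if (e < w) w = e;
    }
    W[j + 1] = w;
  }

  // traceback
  std::string db(n, '.');
  IntegerVector mate(n, 0);
  std::vector<std::array<int, 3> > stack; // (i, j, 0=V 1=M)
  {
    int j = n - 1;
    while (j >= 0) {
      if (W[j + 1] == W[j]) { j--; continue; }
      bool found = false;
      for (int i = 0; i <= j; i++) {
        int pt = ptype(s[i], s[j]);
        if (pt < 0 || V[i][j] >= INF) continue;
        if (W[i] + V[i][j] + termAU(pt) == W[j + 1]) {
          stack.push_back({ i, j, 0 });
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) j--; // defensive; should not happen
    }
  }
  while (!stack.empty()) {
    int i = stack.back()[0], j = stack.back()[1], which = stack.back()[2];
    stack.pop_back();
    if (which == 0) {
      int pt = ptype(s[i], s[j]);
      db[i] = '('; db[j] = ')';
      mate[i] = j + 1; mate[j] = i + 1;
      int e = V[i][j];
      if (e == hairpinE(j - i - 1) + termAU(pt)) continue;
      bool done = false;
      int pmax = std::min(i + MAXLOOP + 1, j - 1 - MINHP);
      for (int p = i + 1; p <= pmax && !done; p++) {
        int n1 = p - i - 1;
        int qmin = std::max(p + MINHP + 1, j - 1 - (MAXLOOP - n1));
        for (int q = j - 1; q >= qmin; q--) {
          if (V[p][q] >= INF) continue;
          int pt2 = ptype(s[p], s[q]);
          if (loopE(n1, j - q - 1, pt, pt2) + V[p][q] == e) {
            stack.push_back({ p, q, 0 });
            done = true;
            break;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k < j - 1; k++) {
        if (M[i + 1][k] >= INF || M[k + 1][j - 1] >= INF) continue;
        if (ML_CLOSE + ML_BRANCH + termAU(pt) + M[i + 1][k] + M[k + 1][j - 1] == e) {
          stack.push_back({ i + 1, k, 1 });
          stack.push_back({ k + 1, j - 1, 1 });
          break;
        }
      }
    } else { // M
      int e = M[i][j];
      if (M[i + 1][j] + ML_UNPAIRED == e && i + 1 <= j) { stack.push_back({ i + 1, j, 1 }); continue; }
      if (M[i][j - 1] + ML_UNPAIRED == e && i <= j - 1) { stack.push_back({ i, j - 1, 1 }); continue; }
      int pt = ptype(s[i], s[j]);
      if (pt >= 0 && V[i][j] < INF && V[i][j] + ML_BRANCH + termAU(pt) == e) {
        stack.push_back({ i, j, 0 });
        continue;
      }
      for (int k = i + 1; k < j; k++) {
        if (M[i][k] >= INF || M[k + 1][j] >= INF) continue;
        if (M[i][k] + M[k + 1][j] == e) {
          stack.push_back({ i, k, 1 });
          stack.push_back({ k + 1, j, 1 });
          break;
        }
      }
    }
  }

  return List::create(_["structure"] = db,
                      _["energy"] = W[n] / 100.0,
                      _["pairmate"] = mate);
}
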