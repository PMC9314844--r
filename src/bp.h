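#ifndef BREEDPROP_BP_H
#define BREEDPROP_BP_H

#include <Rcpp.h>

// Multistate capture-recapture forward pass over the latent classes
// {pre-breeder (age implicit), first-time breeder, experienced breeder,
// skipper, dead}. Observation codes: -1 unavailable, 0 not seen,
// 1 pre-breeder, 2 breeder, 3 skipper.
//
// Rate arrays are indexed by interval (0-based j = transition from study year
// j+1 to j+2, 1-based) with a stride of 0 (constant rate) or 1 (year
// dependent). Detection arrays pY/pP are indexed by detection year y (1-based,
// 2..T) at position (y-2)*stride.
struct CRParams {
  const double *phi0, *phi2, *rho3, *rho4, *rho5, *rho6, *psib, *psis;
  const double *pY, *pP;
  double pR;
  int stride;
};

// Log-likelihood of one history: `obs` has T codes, `ring` is the 1-based
// ringing year (<= 0 for pre-window birds, handled by conditioning on the
// first in-window resighting). Returns 0 for uninformative histories and
// -Inf for structurally impossible ones.
double forward_history(const int* obs, int T, int ring, const CRParams& p);

#endif
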