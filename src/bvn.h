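#ifndef ORDNET_BVN_H
#define ORDNET_BVN_H

double bvn_cdf_scalar(double h, double k, double r);

#endif
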