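// Synthetic reconstruction of the TNF-driven cell-fate decision network:
// death-receptor engagement branches into the NFkB survival pathway, the
// CASP8/CASP3 apoptotic cascade and the RIP1/ROS/MPT non-apoptotic death
// branch.  mRNA intermediates (mXIAP, mROS) carry slowed transcription/
// translation rates ($rt) that delay NFkB's transcriptional feedback.
// This file is a reconstruction assembled from the published cell-fate
// topology, NOT the original model files; rates are package calibrations.

node TNF {
  is_input = TRUE;            // pinned by the coupling layer
}

node TNFR {                    // receptor engagement
  logic = TNF;
  rate_up = $u;
  rate_down = $u;
}

node DISC {                    // death-inducing signalling complex
  logic = TNFR;
  rate_up = $disc_up;
  rate_down = $u;
}

node RIP1 {                    // cleaved/inactivated by CASP8
  logic = TNFR & !CASP8;
  rate_up = $u;
  rate_down = $u;
}

node RIP1ub {                  // ubiquitinated RIP1 scaffolds IKK
  logic = RIP1;
  rate_up = $sf;
  rate_down = $u;
}

node RIP1K {                   // RIP1 kinase activity drives ROS production
  logic = RIP1;
  rate_up = $u;
  rate_down = $u;
}

node IKK {
  logic = RIP1ub;
  rate_up = $sf;
  rate_down = $u;
}

node NFkB {                    // survival transcription factor; cleaved by CASP3
  logic = IKK & !CASP3;
  rate_up = $sf;
  rate_down = $u;
}

node cFLIP {                   // NFkB target, blocks CASP8 activation
  logic = NFkB;
  rate_up = $u;
  rate_down = $u;
}

node CASP8 {
  logic = DISC & !cFLIP;
  rate_up = $casp8_up;
  rate_down = $u;
}

node BCL2 {                    // NFkB target, mitochondrial protection
  logic = NFkB;
  rate_up = $u;
  rate_down = $u;
}

node BAX {
  logic = CASP8 & !BCL2;
  rate_up = $u;
  rate_down = $u;
}

node mROS {                    // transcript of ROS-producing machinery
  logic = RIP1K;
  rate_up = $rt;
  rate_down = $rt;
}

node ROS {
  logic = mROS & RIP1K & !BCL2;
  rate_up = $ros_up;
  rate_down = $u;
}

node MPT {                     // mitochondrial permeability transition
  logic = ROS & !BCL2;          // irreversible once opened
  rate_up = $mpt_up;
  rate_down = 0;
}

node MOMP {
  logic = BAX | MPT;
  rate_up = $u;
  rate_down = $u;
}

node SMAC {
  logic = MOMP;
  rate_up = $u;
  rate_down = $u;
}

node CytC {
  logic = MOMP;
  rate_up = $u;
  rate_down = $u;
}

node mXIAP {                   // XIAP transcript (NFkB target)
  logic = NFkB;
  rate_up = $rt;
  rate_down = $rt;
}

node XIAP {
  logic = mXIAP & !SMAC;
  rate_up = $u;
  rate_down = $u;
}

node ATP {                     // collapses after permeability transition
  logic = !MPT;
  rate_up = $u;
  rate_down = $atp_down;
}

node Apoptosome {
  logic = CytC & ATP & !XIAP;
  rate_up = $u;
  rate_down = $u;
}

node CASP3 {
  logic = Apoptosome & !XIAP;
  rate_up = $u;
  rate_down = $u;
}

node Survival {                // read-out: proliferative cells
  logic = NFkB | !TNF;
  rate_up = $u;
  rate_down = $u;
}

node Apoptosis {               // read-out, irreversible
  logic = CASP3;
  rate_up = $u;
  rate_down = 0;
}

node NonACD {                  // read-out, irreversible (necrosis-like)
  logic = !ATP;
  rate_up = $u;
  rate_down = 0;
}
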