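// Rate calibration and read-out declaration for the synthetic cell-fate
// model.  $u is the protein-event rate scale; $rt the mRNA (transcription/
// translation) rate; $disc_up and $casp8_up slow DISC assembly and CASP8
// activation so the survival and death branches genuinely race.

$u = 0.1;
$sf = 0.2;
$rt = 0.02;
$disc_up = 0.05;
$casp8_up = 0.09;
$ros_up = 0.06;
$mpt_up = 0.06;
$atp_down = 0.02;

// viable starting state: ATP present, proliferative read-out on
ATP.istate = 1;
Survival.istate = 1;

// everything except the three fate read-outs is internal
TNFR.is_internal = TRUE;
DISC.is_internal = TRUE;
RIP1.is_internal = TRUE;
RIP1ub.is_internal = TRUE;
RIP1K.is_internal = TRUE;
IKK.is_internal = TRUE;
NFkB.is_internal = TRUE;
cFLIP.is_internal = TRUE;
CASP8.is_internal = TRUE;
BCL2.is_internal = TRUE;
BAX.is_internal = TRUE;
mROS.is_internal = TRUE;
ROS.is_internal = TRUE;
MPT.is_internal = TRUE;
MOMP.is_internal = TRUE;
SMAC.is_internal = TRUE;
CytC.is_internal = TRUE;
mXIAP.is_internal = TRUE;
XIAP.is_internal = TRUE;
ATP.is_internal = TRUE;
Apoptosome.is_internal = TRUE;
CASP3.is_internal = TRUE;
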