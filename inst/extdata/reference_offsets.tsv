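# Template for mapping deposited HTT17Q-EX1 fusion chains onto the
# 60-residue construct: author numbering minus offset = construct position.
# Offsets depend on how each deposition numbers the fusion carrier; fill in
# per file after inspecting the ATOM records, and validate by loading
# (readPdbChain errors on any sequence mismatch).
label	path	chain	offset
3io4_b	3IO4.pdb	B	NA
3io4_c	3IO4.pdb	C	NA
3io6_b	3IO6.pdb	B	NA
3io6_c	3IO6.pdb	C	NA
3ior_c	3IOR.pdb	C	NA
3iot_a	3IOT.pdb	A	NA
3iot_b	3IOT.pdb	B	NA
3iou_c	3IOU.pdb	C	NA
3iov_b	3IOV.pdb	B	NA
3iov_c	3IOV.pdb	C	NA
3iow_b	3IOW.pdb	B	NA
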