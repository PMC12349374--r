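{"level":3,"width":20,"height":9,"walls":[[0,0],[1,0],[2,0],[3,0],[4,0],[5,0],[6,0],[7,0],[8,0],[9,0],[10,0],[11,0],[12,0],[13,0],[14,0],[15,0],[16,0],[17,0],[18,0],[19,0],[0,1],[19,1],[0,2],[2,2],[3,2],[5,2],[6,2],[7,2],[8,2],[10,2],[11,2],[12,2],[13,2],[15,2],[16,2],[17,2],[19,2],[0,3],[19,3],[0,4],[2,4],[3,4],[5,4],[6,4],[7,4],[8,4],[10,4],[11,4],[12,4],[13,4],[15,4],[16,4],[17,4],[19,4],[0,5],[19,5],[0,6],[2,6],[3,6],[4,6],[5,6],[7,6],[8,6],[9,6],[10,6],[12,6],[13,6],[14,6],[15,6],[17,6],[19,6],[0,7],[19,7],[0,8],[1,8],[2,8],[3,8],[4,8],[5,8],[6,8],[7,8],[8,8],[9,8],[10,8],[11,8],[12,8],[13,8],[14,8],[15,8],[16,8],[17,8],[18,8],[19,8]],"start":[1,1],"finish":[[15,7],[16,7]],"zones":{"1":[[4,1]],"2":[[9,1]],"3":[[14,1]],"4":[[2,3]],"5":[[7,3]],"6":[[12,3]],"7":[[17,3]],"8":[[3,5]],"9":[[8,5]],"10":[[13,5]],"11":[[3,7]]},"checkpoints":["6","11","F"]}
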