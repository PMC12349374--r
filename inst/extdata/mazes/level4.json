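{"level":4,"width":20,"height":10,"walls":[[0,0],[1,0],[2,0],[3,0],[4,0],[5,0],[6,0],[7,0],[8,0],[9,0],[10,0],[11,0],[12,0],[13,0],[14,0],[15,0],[16,0],[17,0],[18,0],[19,0],[0,1],[8,1],[19,1],[0,2],[2,2],[3,2],[4,2],[5,2],[6,2],[8,2],[10,2],[11,2],[12,2],[13,2],[15,2],[16,2],[17,2],[19,2],[0,3],[6,3],[8,3],[13,3],[17,3],[19,3],[0,4],[6,4],[8,4],[13,4],[17,4],[19,4],[0,5],[2,5],[3,5],[4,5],[6,5],[8,5],[10,5],[11,5],[13,5],[15,5],[17,5],[19,5],[0,6],[2,6],[6,6],[10,6],[13,6],[15,6],[19,6],[0,7],[2,7],[4,7],[5,7],[6,7],[7,7],[8,7],[10,7],[12,7],[13,7],[15,7],[16,7],[17,7],[19,7],[0,8],[10,8],[19,8],[0,9],[1,9],[2,9],[3,9],[4,9],[5,9],[6,9],[7,9],[8,9],[9,9],[10,9],[11,9],[12,9],[13,9],[14,9],[15,9],[16,9],[17,9],[18,9],[19,9]],"start":[1,1],"finish":[[17,8],[18,8]],"zones":{"1":[[4,1]],"2":[[12,1]],"3":[[3,4]],"4":[[10,4]],"5":[[15,4]],"6":[[4,8]],"7":[[8,8]]},"checkpoints":["3","7","F"]}
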